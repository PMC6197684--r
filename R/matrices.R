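#' Construct a transition matrix object
#'
#' A transition matrix gives, in row \code{i} and column \code{j}, the
#' probability \eqn{p(s^t = j \mid s^{t-1} = i)} that stimulus \code{j}
#' follows stimulus \code{i}.  Matrices are classified by their dynamics:
#' \describe{
#'   \item{zeroth}{memoryless: all four rows identical, one predominant
#'     next symbol regardless of the previous one.}
#'   \item{first}{the predominant next symbol depends on the previous one;
#'     the high-probability transitions form a cycle visiting all four
#'     stimuli.}
#'   \item{alternating}{first-order dynamics whose high-probability
#'     transitions pair stimuli into two period-2 cycles.}
#' }
#'
#' @param id integer identifier (1-8 in the default task design).
#' @param dynamics one of \code{"zeroth"}, \code{"first"}, \code{"alternating"}.
#' @param T a 4x4 row-stochastic matrix of transition probabilities.
#' @return an object of class \code{transition_matrix}.
#' @export
transition_matrix <- function(id, dynamics = c("zeroth", "first", "alternating"), T) {
  dynamics <- match.arg(dynamics)
  T <- as.matrix(T)
  if (!all(dim(T) == c(4L, 4L)))
    stop("transition matrix must be 4x4")
  if (any(T < 0))
    stop("transition probabilities must be nonnegative")
  if (any(abs(rowSums(T) - 1) > 1e-12))
    stop("every row of a transition matrix must sum to 1")
  if (dynamics == "zeroth" &&
      any(abs(sweep(T, 2, T[1L, ])) > 1e-12))
    stop("a zeroth-order matrix must have identical rows")
  structure(list(id = as.integer(id), dynamics = dynamics, T = unname(T)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Transition matrix %d (%s-order dynamics)\n", x$id,
              switch(x$dynamics, zeroth = "0th", first = "1st", x$dynamics)))
  print(round(x$T, 4))
  invisible(x)
}

# one row: p_high on `target`, remaining mass uniform over the other columns
.row_with_peak <- function(target, p_high) {
  row <- rep((1 - p_high) / 3, 4L)
  row[target] <- p_high
  row
}

#' Default battery of eight task transition matrices
#'
#' Builds the standard task battery: four zeroth-order matrices (one per
#' predominant symbol), two first-order matrices whose predominant
#' transitions trace a 4-cycle over all stimuli, and two alternating
#' matrices whose predominant transitions form two disjoint stimulus
#' pairs.  In every row the predominant transition has probability
#' \code{p_high} and the remaining mass is spread uniformly over the other
#' three columns.
#'
#' @param p_high probability of the predominant transition in each row,
#'   in \code{[0.25, 1]}.  At 0.25 all matrices degenerate to uniform.
#' @param first_cycles list of two integer permutations of 1:4; entry
#'   \code{k} of a cycle is the predominant successor of stimulus \code{k}.
#'   Each must visit all four stimuli in one cycle.
#' @param alternating_pairs list of two pairings, each a permutation of 1:4
#'   composed of two disjoint transpositions.
#' @return list of 8 \code{transition_matrix} objects.
#' @export
default_matrices <- function(p_high = 0.7,
                             first_cycles = list(c(2L, 3L, 4L, 1L),
                                                 c(3L, 4L, 2L, 1L)),
                             alternating_pairs = list(c(2L, 1L, 4L, 3L),
                                                      c(4L, 3L, 2L, 1L))) {
  if (!is.numeric(p_high) || length(p_high) != 1L ||
      p_high < 0.25 || p_high > 1)
    stop("p_high must be a probability in [0.25, 1]")
  .check_successor <- function(succ, cycle) {
    if (!identical(sort(as.integer(succ)), 1:4))
      stop("successor maps must be permutations of 1:4")
    # orbit of 1 must have length 4 for a cycle, 2 for a pairing
    orbit <- 1L
    for (i in 1:4) orbit <- c(orbit, succ[orbit[length(orbit)]])
    len <- which(orbit[-1L] == 1L)[1L]
    if (cycle && len != 4L)
      stop("first-order successor map must be a single 4-cycle")
    if (!cycle && (!identical(as.integer(succ[succ]), 1:4) ||
                   any(succ == 1:4)))
      stop("alternating successor map must pair all stimuli into two 2-cycles")
    invisible(succ)
  }
  lapply(first_cycles, .check_successor, cycle = TRUE)
  lapply(alternating_pairs, .check_successor, cycle = FALSE)

  mats <- vector("list", 8L)
  for (k in 1:4)
    mats[[k]] <- transition_matrix(k, "zeroth",
                                   matrix(.row_with_peak(k, p_high), 4L, 4L,
                                          byrow = TRUE))
  for (m in 1:2) {
    succ <- first_cycles[[m]]
    T <- t(vapply(1:4, function(i) .row_with_peak(succ[i], p_high),
                  numeric(4L)))
    mats[[4L + m]] <- transition_matrix(4L + m, "first", T)
  }
  for (m in 1:2) {
    succ <- alternating_pairs[[m]]
    T <- t(vapply(1:4, function(i) .row_with_peak(succ[i], p_high),
                  numeric(4L)))
    mats[[6L + m]] <- transition_matrix(6L + m, "alternating", T)
  }
  mats
}

#' Task design: matrices, block structure and schedule constraints
#'
#' @param matrices list of \code{transition_matrix} objects
#'   (default \code{\link{default_matrices}}).
#' @param block_length trials per block (default 50).
#' @param repeats_per_matrix how often each matrix is scheduled (default 3).
#' @param p_high predominant transition probability used to build the
#'   default matrices.
#' @return an object of class \code{task_design}.
#' @export
task_design <- function(matrices = default_matrices(p_high),
                        block_length = 50L,
                        repeats_per_matrix = 3L,
                        p_high = 0.7) {
  if (block_length < 1L) stop("block_length must be >= 1")
  if (repeats_per_matrix < 1L) stop("repeats_per_matrix must be >= 1")
  stopifnot(all(vapply(matrices, inherits, logical(1), "transition_matrix")))
  structure(list(matrices = matrices,
                 block_length = as.integer(block_length),
                 repeats_per_matrix = as.integer(repeats_per_matrix),
                 p_high = p_high,
                 # stimulus timing, metadata only (plays no computational role)
                 stim_duration_ms = 200, isi_ms = 1200),
            class = "task_design")
}

# matrix lookup by id
.design_matrix <- function(design, id) {
  ids <- vapply(design$matrices, `[[`, integer(1), "id")
  design$matrices[[match(id, ids)]]
}
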