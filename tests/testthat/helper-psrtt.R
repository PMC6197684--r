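# shared fixtures, built in code

# placebo-group point estimates used as generative values throughout
placebo_params <- function(...)
  fom_params(lambda = 0.303, gamma = 1, beta0 = 6.671, beta1 = -1.248,
             beta2 = 0.0445, ...)

# a small session: n_blocks of the default design under a fixed seed
small_session <- function(n_blocks = 6, seed = 11, design = task_design()) {
  set.seed(seed)
  sched <- sample_schedule(design)[seq_len(n_blocks)]
  generate_sequence(sched, design)
}

# a minimal hand-built trial table (single zeroth-order block, matrix 2)
toy_trials <- function(stim, block = 1L, matrix_id = 2L, rt_ms = NULL,
                       correct = NULL, valid = NULL) {
  n <- length(stim)
  data.frame(trial = seq_len(n), block = block, matrix_id = matrix_id,
             prev_stim = c(NA_integer_, stim[-n]), stim = stim,
             correct = if (is.null(correct)) rep(TRUE, n) else correct,
             valid = if (is.null(valid)) rep(TRUE, n) else valid,
             rt_ms = if (is.null(rt_ms)) rep(400, n) else rt_ms)
}

# synthetic null run table: n_subj subjects, n_runs runs each of length
# run_len, iid standard normal zlogrt, alternating half labels
null_runs <- function(n_subj = 8, n_runs = 12, run_len = 3) {
  do.call(rbind, lapply(seq_len(n_subj), function(s) {
    do.call(rbind, lapply(seq_len(n_runs), function(r) {
      data.frame(subject_id = sprintf("s%d", s), block = r,
                 run = (s - 1) * n_runs + r, start_trial = 1L,
                 half = if (r %% 2 == 0) "second" else "first",
                 pos = seq_len(run_len), trial = seq_len(run_len),
                 source = "data", zlogrt = rnorm(run_len))
    }))
  }))
}
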