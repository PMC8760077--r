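# Synthetic-data generators with ground truth. Each generator emulates the
# statistical structure the downstream analysis assumes: Poisson spectral
# counts with a bead-binder background and a trap-enriched spike-in
# subpopulation, saturating FRAP recovery with Gaussian noise, and
# multiplicatively independent dose-response surfaces with an optional
# supra-additive bonus.

#' Simulation configuration
#'
#' One configuration object drives all three generators. All randomness is a
#' pure function of `seed`: each generator derives its own stream from the
#' top-level seed by a fixed offset, so tables, traces and grids are
#' reproducible individually and jointly.
#'
#' @param seed integer master seed.
#' @param n_background number of background proteins detected in both
#'   conditions regardless of trapping.
#' @param n_spiked number of true trap-enriched interactors.
#' @param lambda_bg mean background PSM count (Poisson rate).
#' @param fold trap-condition PSM fold enrichment of spiked proteins.
#' @param n_bead_binders number of sticky proteins present in the
#'   bait-negative control with high unique-peptide counts.
#' @param dropout_ref probability that a spiked protein goes undetected in
#'   the reference sample (the pseudocount case).
#' @param low_abundance_frac fraction of background proteins drawn at a low
#'   rate (1.5) so single-peptide rows occur.
#' @param overdispersion negative-binomial overdispersion; 0 (default) gives
#'   pure Poisson counts.
#' @param frap list: `n_traces` (10, typical cells per condition), `t_half`
#'   seconds, `ymax` plateau, `sigma` Gaussian intensity noise on the
#'   normalised scale, `dt` frame interval seconds (2, the acquisition
#'   interval), `t_max` seconds.
#' @param viability list: `doses_a`, `doses_b` (must start at 0),
#'   `effects_a`, `effects_b` true monotherapy effects in \[0, 1\] aligned
#'   with the doses, `bonus` supra-additive interaction (scalar applied to
#'   all combination cells, or a full dose x dose matrix), `sigma` additive
#'   viability noise, `n_replicates`, `vehicle_signal` raw signal scale.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_background = 500L, n_spiked = 50L,
                       lambda_bg = 10, fold = 4,
                       n_bead_binders = 30L, dropout_ref = 0.2,
                       low_abundance_frac = 0.1,
                       overdispersion = 0,
                       frap = list(), viability = list()) {
  frap_defaults <- list(n_traces = 10L, t_half = 5, ymax = 0.8,
                        sigma = 0.05, dt = 2, t_max = 60)
  via_defaults <- list(doses_a = c(0, 10, 50, 100, 250),
                       doses_b = c(0, 25, 100, 250),
                       effects_a = c(0, 0.15, 0.35, 0.55, 0.75),
                       effects_b = c(0, 0.10, 0.30, 0.50),
                       bonus = 0, sigma = 0.02, n_replicates = 3L,
                       vehicle_signal = 10000)
  frap <- utils::modifyList(frap_defaults, frap)
  viability <- utils::modifyList(via_defaults, viability)
  cfg <- list(seed = as.integer(seed), n_background = as.integer(n_background),
              n_spiked = as.integer(n_spiked), lambda_bg = lambda_bg,
              fold = fold, n_bead_binders = as.integer(n_bead_binders),
              dropout_ref = dropout_ref,
              low_abundance_frac = low_abundance_frac,
              overdispersion = overdispersion,
              frap = frap, viability = viability)
  with(cfg, {
    stopifnot(n_background >= 0, n_spiked >= 0, n_bead_binders >= 0,
              lambda_bg >= 0, fold >= 0, overdispersion >= 0)
    if (dropout_ref < 0 || dropout_ref > 1 ||
        low_abundance_frac < 0 || low_abundance_frac > 1)
      validation_error("probabilities must lie in [0, 1]")
  })
  if (frap$t_half <= 0 || frap$ymax <= 0 || frap$sigma < 0 || frap$dt <= 0)
    validation_error("frap config needs t_half > 0, ymax > 0, sigma >= 0, dt > 0")
  v <- viability
  if (length(v$effects_a) != length(v$doses_a) ||
      length(v$effects_b) != length(v$doses_b))
    validation_error("viability effects must align with their dose vectors")
  if (v$doses_a[1] != 0 || v$doses_b[1] != 0 ||
      v$effects_a[1] != 0 || v$effects_b[1] != 0)
    validation_error("dose vectors must start at 0 with effect 0")
  if (any(v$effects_a < 0 | v$effects_a > 1) ||
      any(v$effects_b < 0 | v$effects_b > 1) ||
      any(v$bonus < 0 | v$bonus >= 1) || v$sigma < 0)
    validation_error("viability effects and bonus must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

# Derived per-generator seed streams; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) * 1000003 + offset) %% 2147483647)
}

rcounts <- function(n, lambda, overdispersion) {
  if (n == 0L) return(integer(0))
  if (overdispersion > 0)
    stats::rnbinom(n, mu = lambda, size = 1 / overdispersion)
  else
    stats::rpois(n, lambda)
}

peptides_from_psms <- function(psms) pmax(1L, as.integer(ceiling(psms / 2)))

score_from_psms <- function(psms) round(psms * stats::runif(length(psms), 25, 40), 1)

sim_psm_records <- function(accession, gene_symbol, psms) {
  keep <- psms > 0L
  data.frame(accession = accession[keep],
             gene_symbol = gene_symbol[keep],
             unique_peptides = peptides_from_psms(psms[keep]),
             psms = as.integer(psms[keep]),
             ms_score = score_from_psms(psms[keep]),
             stringsAsFactors = FALSE)
}

#' Simulate a trap/reference/control interactome experiment
#'
#' Background proteins draw Poisson(`lambda_bg`) PSMs in both conditions (a
#' `low_abundance_frac` slice draws at rate 1.5 so the single-peptide filter
#' has work to do). Spiked interactors draw Poisson(`fold * lambda_bg`) under
#' trapping and Poisson(`lambda_bg`) in the reference, going undetected there
#' with probability `dropout_ref`. Bead binders appear in all three samples;
#' in the bait-negative control they carry at least 3 unique peptides so the
#' background-subtraction rule removes them. Unique peptides are tied to
#' PSMs by `ceiling(psms / 2)` (min 1) and the protein score rises with PSMs
#' plus noise.
#'
#' The study design this emulates ran each experiment in three independent
#' replicates; pass `replicate = 1, 2, 3` to draw the replicate tables (each
#' replicate gets its own deterministic stream) and pool them with
#' [aggregate_replicates()].
#'
#' @param cfg a [sim_config()].
#' @param replicate replicate index (deterministic stream offset).
#' @return List with `ident_table`s `trap`, `ref`, `control`, and `truth`
#'   (class `sim_truth`: `spiked`, `bead_binders` accession vectors and the
#'   generating config).
#' @export
simulate_interactome <- function(cfg, replicate = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    validation_error("replicate must be a positive integer")
  set.seed(derive_seed(cfg$seed, 11L + 1000L * replicate))
  n_low <- round(cfg$n_background * cfg$low_abundance_frac)
  n_hi <- cfg$n_background - n_low
  bg_acc <- sprintf("BG%05d", seq_len(cfg$n_background))
  bg_lambda <- c(rep(cfg$lambda_bg, n_hi), rep(1.5, n_low))
  spk_acc <- if (cfg$n_spiked) sprintf("SPK%04d", seq_len(cfg$n_spiked)) else character(0)
  bead_acc <- if (cfg$n_bead_binders) sprintf("BEAD%03d", seq_len(cfg$n_bead_binders)) else character(0)
  sym <- function(acc) paste0("G", acc)

  bg_trap <- rcounts(cfg$n_background, bg_lambda, cfg$overdispersion)
  bg_ref  <- rcounts(cfg$n_background, bg_lambda, cfg$overdispersion)
  spk_trap <- rcounts(cfg$n_spiked, cfg$fold * cfg$lambda_bg, cfg$overdispersion)
  spk_ref  <- rcounts(cfg$n_spiked, cfg$lambda_bg, cfg$overdispersion)
  spk_ref[stats::runif(cfg$n_spiked) < cfg$dropout_ref] <- 0L
  bead_trap <- rcounts(cfg$n_bead_binders, cfg$lambda_bg, cfg$overdispersion) + 1L
  bead_ref  <- rcounts(cfg$n_bead_binders, cfg$lambda_bg, cfg$overdispersion) + 1L
  # control: bead binders abundant (>= 3 unique peptides guaranteed), plus a
  # thin slice of ordinary background at <= 2 unique peptides (psms <= 4)
  bead_ctrl <- 5L + rcounts(cfg$n_bead_binders, cfg$lambda_bg, cfg$overdispersion)
  n_ctrl_bg <- round(0.2 * cfg$n_background)
  ctrl_bg_idx <- if (n_ctrl_bg) sort(sample.int(cfg$n_background, n_ctrl_bg)) else integer(0)
  ctrl_bg <- if (n_ctrl_bg) sample(1:4, n_ctrl_bg, replace = TRUE) else integer(0)

  trap_records <- sim_psm_records(c(bg_acc, spk_acc, bead_acc),
                               sym(c(bg_acc, spk_acc, bead_acc)),
                               c(bg_trap, spk_trap, bead_trap))
  ref_records <- sim_psm_records(c(bg_acc, spk_acc, bead_acc),
                              sym(c(bg_acc, spk_acc, bead_acc)),
                              c(bg_ref, spk_ref, bead_ref))
  ctrl_records <- sim_psm_records(c(bead_acc, bg_acc[ctrl_bg_idx]),
                               sym(c(bead_acc, bg_acc[ctrl_bg_idx])),
                               c(bead_ctrl, ctrl_bg))
  list(
    trap = identification_table(trap_records,
                                sprintf("sim_trap_r%d", replicate),
                                bait = "wt", condition = "trap",
                                replicate = replicate),
    ref = identification_table(ref_records,
                               sprintf("sim_ref_r%d", replicate),
                               bait = "wt", condition = "reference",
                               replicate = replicate),
    control = identification_table(ctrl_records,
                                   sprintf("sim_control_r%d", replicate),
                                   bait = "parental", condition = "control",
                                   replicate = replicate),
    truth = structure(list(spiked = spk_acc, bead_binders = bead_acc,
                           config = cfg), class = "sim_truth"))
}

#' Simulate FRAP recovery traces
#'
#' Traces follow the one-site binding recovery `ymax * t / (t_half + t)` on
#' the normalised scale, with i.i.d. Gaussian noise of s.d. `sigma` on every
#' frame after the bleach anchor, then an affine transform onto a raw
#' intensity scale (per-trace pre-bleach level near 1000, bleach depth near
#' 80%), so normalisation is exercised.
#'
#' @param cfg a [sim_config()]; the `frap` sub-config applies. Override
#'   fields per call via `...`, e.g. `simulate_frap(cfg, t_half = 10)`.
#' @param ... named overrides of the `frap` sub-config.
#' @return List with `traces` (list of un-normalised `frap_trace`s) and
#'   `truth` (the generating parameters).
#' @export
simulate_frap <- function(cfg, ...) {
  stopifnot(inherits(cfg, "sim_config"))
  fc <- utils::modifyList(cfg$frap, list(...))
  if (fc$t_half <= 0) validation_error("t_half must be positive")
  set.seed(derive_seed(cfg$seed, 23L))
  times <- seq(0, fc$t_max, by = fc$dt)
  traces <- lapply(seq_len(fc$n_traces), function(i) {
    pre <- stats::runif(1, 900, 1100)
    post <- pre * stats::runif(1, 0.15, 0.25)
    y <- one_site_model(times, fc$ymax, fc$t_half)
    y[-1] <- y[-1] + stats::rnorm(length(times) - 1L, 0, fc$sigma)
    raw <- post + (pre - post) * y
    raw[1] <- post   # bleach anchor frame carries no noise by definition
    frap_trace(times, raw, prebleach_value = pre, postbleach_value = post,
               id = sprintf("trace%03d", i))
  })
  list(traces = traces,
       truth = list(t_half = fc$t_half, ymax = fc$ymax, sigma = fc$sigma))
}

#' Simulate a dose-pair viability grid
#'
#' True combination viability is multiplicative,
#' `(1 - E_A)(1 - E_B)(1 - bonus)`, so `bonus = 0` constructs exact Bliss
#' independence. Gaussian noise of s.d. `sigma` is added on the viability
#' scale per replicate, and measurements are emitted as raw signals around
#' `vehicle_signal` so vehicle normalisation is exercised.
#'
#' @param cfg a [sim_config()]; the `viability` sub-config applies, with
#'   named overrides via `...`.
#' @param ... named overrides of the `viability` sub-config.
#' @return List with `grid` (a `viability_grid`), `long` (the raw long-format
#'   measurement table) and `truth` (true viability/effect matrices, the
#'   bonus matrix and the monotherapy effects).
#' @export
simulate_viability <- function(cfg, ...) {
  stopifnot(inherits(cfg, "sim_config"))
  v <- utils::modifyList(cfg$viability, list(...))
  set.seed(derive_seed(cfg$seed, 37L))
  na <- length(v$doses_a); nb <- length(v$doses_b)
  bonus <- v$bonus
  if (length(bonus) == 1L) {
    bonus <- matrix(0, na, nb)
    bonus[outer(v$doses_a > 0, v$doses_b > 0, `&`)] <- v$bonus
  } else {
    bonus <- matrix(bonus, na, nb)
  }
  v_true <- outer(1 - v$effects_a, 1 - v$effects_b) * (1 - bonus)
  rows <- list()
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    obs <- v_true[i, j] + stats::rnorm(v$n_replicates, 0, v$sigma)
    rows[[length(rows) + 1L]] <- data.frame(
      dose_a = v$doses_a[i], dose_b = v$doses_b[j],
      replicate = seq_len(v$n_replicates),
      signal = pmax(obs, 0) * v$vehicle_signal)
  }
  long <- do.call(rbind, rows)
  list(grid = as_viability_grid(long), long = long,
       truth = list(viability = v_true, effect = 1 - v_true, bonus = bonus,
                    effects_a = v$effects_a, effects_b = v$effects_b))
}
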