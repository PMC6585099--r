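#' Configure a synthetic two-group Ct panel
#'
#' Describes the generative model for a synthetic qPCR panel emulating a
#' 754-probe two-group (25 vs 25) miRNA OpenArray experiment: per-probe
#' baselines, per-sample global loading shifts, probe variances from a scaled
#' inverse-chi-square prior, spiked log2 group effects on a subset of probes,
#' a set of near-constant endogenous-control candidates, and right-censoring
#' of non-detection at Ct = 40.
#'
#' @param n_probes Number of probes on the panel (default 754).
#' @param n_case,n_control Group sizes (default 25 each).
#' @param frac_never_detected Fraction of probes set to the censoring ceiling
#'   in every sample (default 0.30, emulating the roughly half of panel
#'   probes never detected in fluid-derived EV RNA).
#' @param n_de Number of truly dysregulated probes (default 210).
#' @param effect_log2 Optional numeric vector of length `n_de` of signed log2
#'   expression effects (positive = up in cases). When `NULL`, magnitudes are
#'   drawn uniformly from \code{[1, 8]} at simulation time, with the
#'   case-down fraction matching the 207/210 regime of real EV panels.
#' @param d0,s0_sq Hyperparameters of the scaled inverse-chi-square variance
#'   prior: probe variances are drawn as \code{s0_sq * d0 / chisq(d0)}
#'   (defaults 4 and 0.25).
#' @param sample_shift_sd Standard deviation of per-sample additive Ct shifts
#'   (default 2, a strong loading effect that delta normalization must
#'   remove).
#' @param n_controls_true Number of planted near-constant control-candidate
#'   probes (default 4).
#' @param control_var Within-group variance of the planted controls (default
#'   1e-3; clamped below the smallest non-control variance so the controls
#'   are strictly the most stable probes).
#' @param censor_ceiling Ct value encoding non-detection (fixed at 40 on this
#'   platform).
#' @param seed Master seed; sub-streams for variances, baselines, effects,
#'   shifts and noise are derived deterministically from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 754, n_case = 25, n_control = 25,
                       frac_never_detected = 0.30, n_de = 210,
                       effect_log2 = NULL, d0 = 4, s0_sq = 0.25,
                       sample_shift_sd = 2, n_controls_true = 4,
                       control_var = 1e-3, censor_ceiling = 40, seed = 1) {
  cfg <- list(n_probes = as.integer(n_probes), n_case = as.integer(n_case),
              n_control = as.integer(n_control),
              frac_never_detected = frac_never_detected,
              n_de = as.integer(n_de), effect_log2 = effect_log2,
              d0 = d0, s0_sq = s0_sq, sample_shift_sd = sample_shift_sd,
              n_controls_true = as.integer(n_controls_true),
              control_var = control_var, censor_ceiling = censor_ceiling,
              seed = seed)
  with(cfg, {
    if (n_probes <= 0 || n_case <= 0 || n_control <= 0) {
      stop_("counts must be positive")
    }
    if (frac_never_detected < 0 || frac_never_detected >= 1) {
      stop_("frac_never_detected must be in [0, 1)")
    }
    if (d0 <= 0 || s0_sq <= 0) stop_("d0 and s0_sq must be positive")
    if (sample_shift_sd < 0) stop_("sample_shift_sd must be >= 0")
    if (n_de < 0 || n_controls_true < 0) stop_("n_de / n_controls_true must be >= 0")
    if (n_de + n_controls_true > n_probes) {
      stop_("n_de + n_controls_true exceeds n_probes")
    }
    if (!is.null(effect_log2)) {
      if (length(effect_log2) != n_de) stop_("effect_log2 must have length n_de")
      if (any(effect_log2 == 0)) stop_("effects of dysregulated probes must be nonzero")
    }
  })
  structure(cfg, class = "sim_config")
}

#' Draw probe variances from the scaled inverse-chi-square prior
#'
#' Returns `m` independent draws of \code{s0_sq * d0 / chisq(d0)}, the
#' variance prior underlying the empirical-Bayes moderated-t model.
#'
#' @param m Number of draws.
#' @param d0 Prior degrees of freedom (> 0).
#' @param s0_sq Prior scale (> 0).
#' @param seed Optional seed (caller RNG state is restored).
#' @return Positive numeric vector of length `m`.
#' @export
sample_probe_variances <- function(m, d0, s0_sq, seed = NULL) {
  if (m <= 0 || d0 <= 0 || s0_sq <= 0) stop_("m, d0 and s0_sq must be positive")
  with_seed(seed, s0_sq * d0 / stats::rchisq(m, df = d0))
}

#' Simulate a two-group Ct panel with known ground truth
#'
#' Generates \code{Ct[g, i] = baseline_g + shift_i - effect_g * 1\{i case\} +
#' eps_gi} with \code{eps_gi ~ N(0, var_g)} and \code{var_g} from the scaled
#' inverse-chi-square prior; a `frac_never_detected` subset of probes is set
#' to the ceiling in every sample, and all values are clipped to
#' \code{[0, ceiling]} with values at or above the ceiling coded exactly as
#' the ceiling. Effects are injected on the Ct scale with a sign flip
#' (expression up means Ct down) so downstream logFC orientation can be
#' validated end to end. Planted controls have effect 0, variance below
#' every other probe, and mid-range baselines; they are never force-censored.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Optional override of `config$seed`.
#' @return List with elements `ct` (Ct matrix), `annotation` (sample_id /
#'   group data frame, cases first) and `truth` (class `sim_truth`: de probe
#'   ids, signed per-probe effects, true variances, control probe ids,
#'   per-sample shifts, never-detected probe ids).
#' @export
simulate_panel <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  n <- config$n_probes
  ns <- config$n_case + config$n_control
  probe_ids <- sprintf("probe_%04d", seq_len(n))
  sample_ids <- c(sprintf("case_%02d", seq_len(config$n_case)),
                  sprintf("control_%02d", seq_len(config$n_control)))
  is_case <- c(rep(1, config$n_case), rep(0, config$n_control))

  # probe role assignment: controls, dysregulated, never-detected (disjoint)
  n_cens <- round(config$frac_never_detected * n)
  if (config$n_de + config$n_controls_true + n_cens > n) {
    stop_("frac_never_detected leaves too few probes for DE and control roles")
  }
  assign_ids <- with_seed(derive_seed(seed, "assign"), {
    perm <- sample(probe_ids)
    list(control = perm[seq_len(config$n_controls_true)],
         de = perm[config$n_controls_true + seq_len(config$n_de)],
         censored = if (n_cens > 0) {
           perm[config$n_controls_true + config$n_de + seq_len(n_cens)]
         } else character(0))
  })

  var_g <- sample_probe_variances(n, config$d0, config$s0_sq,
                                  seed = derive_seed(seed, "variances"))
  names(var_g) <- probe_ids
  idx_ctrl <- match(assign_ids$control, probe_ids)
  if (length(idx_ctrl)) {
    floor_var <- min(var_g[-idx_ctrl]) / 2
    var_g[idx_ctrl] <- min(config$control_var, floor_var)
  }

  baseline <- with_seed(derive_seed(seed, "baselines"), stats::runif(n, 22, 33))
  names(baseline) <- probe_ids
  # controls sit in the well-detected mid range, far from the ceiling
  baseline[idx_ctrl] <- with_seed(derive_seed(seed, "ctrl_baselines"),
                                  stats::runif(length(idx_ctrl), 22, 28))

  effect <- stats::setNames(numeric(n), probe_ids)
  if (config$n_de > 0) {
    eff <- config$effect_log2
    if (is.null(eff)) {
      eff <- with_seed(derive_seed(seed, "effects"), {
        n_up <- round(config$n_de * 3 / 210)
        sgn <- rep(-1, config$n_de)
        if (n_up > 0) sgn[sample.int(config$n_de, n_up)] <- 1
        sgn * stats::runif(config$n_de, 1, 8)
      })
    }
    effect[assign_ids$de] <- eff
  }

  shift <- with_seed(derive_seed(seed, "shifts"),
                     stats::rnorm(ns, 0, config$sample_shift_sd))
  names(shift) <- sample_ids

  eps <- with_seed(derive_seed(seed, "noise"),
                   matrix(stats::rnorm(n * ns, 0, sqrt(var_g)), n, ns))
  ct <- baseline + outer(-effect, is_case) + rep(shift, each = n) + eps
  dimnames(ct) <- list(probe_ids, sample_ids)
  ct[assign_ids$censored, ] <- config$censor_ceiling
  ct[ct >= config$censor_ceiling] <- config$censor_ceiling
  ct[ct < 0] <- 0
  if (mean(ct == config$censor_ceiling) > 0.95) {
    stop_("unusable configuration: clipping censors more than 95% of entries")
  }

  annotation <- data.frame(
    sample_id = sample_ids,
    group = ifelse(is_case == 1, "case", "control"),
    stringsAsFactors = FALSE
  )
  truth <- structure(list(
    de_probe_ids = assign_ids$de,
    effect_log2_by_probe = effect,
    true_variances = var_g,
    control_probe_ids = assign_ids$control,
    sample_shifts = shift,
    never_detected_ids = assign_ids$censored
  ), class = "sim_truth")
  list(ct = ct, annotation = annotation, truth = truth)
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth A `sim_truth` object.
#' @param path File path.
#' @return `read_sim_truth` returns a `sim_truth` list.
#' @export
write_sim_truth <- function(truth, path) {
  x <- unclass(truth)
  named <- c("effect_log2_by_probe", "true_variances", "sample_shifts")
  x[named] <- lapply(x[named], as.list)  # keep names: JSON object, not array
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  named <- c("effect_log2_by_probe", "true_variances", "sample_shifts")
  x[named] <- lapply(x[named], unlist)
  structure(x, class = "sim_truth")
}
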