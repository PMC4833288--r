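# run expr under a fixed seed, leaving the caller's RNG state untouched
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulation parameters for FRAP traces
#'
#' Defaults describe the emulated acquisition: a 12-bit-scale plateau around
#' 1000 AU, a bleach pulse leaving 20% of the signal, single-exponential
#' recovery in half-time parameterization, frames every 0.5 s, 10 pre-bleach
#' frames and an 80-frame (40 s) post-bleach window. The window extends well
#' past the ~30 s in which recovery completes so that the last-five-frame
#' plateau estimator carries negligible truncation bias
#' (about `M * 2^(-38/tau)`, under 0.5% of `M` at `tau = 5` s).
#'
#' @param prebleach_level Pre-bleach intensity (AU).
#' @param bleach_depth Fraction of signal remaining right after the bleach.
#' @param mobile_fraction_true True mobile fraction `M` in \[0, 1\].
#' @param t_half_true True recovery half-time `tau` (s, > 0).
#' @param acq_bleach_slope Fractional acquisition-bleaching loss per second.
#' @param noise_sd Additive Gaussian noise sd (AU).
#' @param frame_interval Frame spacing (s).
#' @param n_prebleach_frames Frames before the bleach (>= 5).
#' @param n_postbleach_frames Frames from the bleach frame onward.
#' @param n_worms Number of worms.
#' @param seed RNG seed.
#' @return A validated list of class `frap_sim_params`.
#' @export
frap_sim_params <- function(prebleach_level = 1000, bleach_depth = 0.2,
                            mobile_fraction_true = 0.8, t_half_true = 5,
                            acq_bleach_slope = 0, noise_sd = 0,
                            frame_interval = 0.5, n_prebleach_frames = 10,
                            n_postbleach_frames = 80, n_worms = 10, seed = 1) {
  stopifnot(prebleach_level > 0,
            bleach_depth >= 0, bleach_depth <= 1,
            mobile_fraction_true >= 0, mobile_fraction_true <= 1,
            t_half_true > 0, acq_bleach_slope >= 0, noise_sd >= 0,
            frame_interval > 0, n_prebleach_frames >= 5,
            n_postbleach_frames >= 1, n_worms >= 1)
  structure(list(prebleach_level = prebleach_level, bleach_depth = bleach_depth,
                 mobile_fraction_true = mobile_fraction_true,
                 t_half_true = t_half_true, acq_bleach_slope = acq_bleach_slope,
                 noise_sd = noise_sd, frame_interval = frame_interval,
                 n_prebleach_frames = as.integer(n_prebleach_frames),
                 n_postbleach_frames = as.integer(n_postbleach_frames),
                 n_worms = as.integer(n_worms), seed = as.integer(seed)),
            class = "frap_sim_params")
}

#' Generate synthetic FRAP traces with known truth
#'
#' The ideal bleached-ROI signal is the pre-bleach plateau `P` before the
#' bleach frame and
#' \eqn{P [b + M (1 - b)(1 - 2^{-(t - t_b)/\tau})]} from the bleach frame
#' onward; acquisition bleaching multiplies both regions by `(1 - s t)` and
#' Gaussian noise is added. The reference region is `P (1 - s t)` plus noise.
#'
#' @param params A [frap_sim_params()].
#' @return List with `traces` (list of [frap_trace()]) and `truth` (data
#'   frame of the true `t_half` and `mobile_fraction` per worm).
#' @export
gen_frap_traces <- function(params = frap_sim_params()) {
  stopifnot(inherits(params, "frap_sim_params"))
  p <- params
  n_frames <- p$n_prebleach_frames + p$n_postbleach_frames
  times <- (seq_len(n_frames) - 1) * p$frame_interval
  bleach_idx <- p$n_prebleach_frames + 1L
  t_b <- times[bleach_idx]
  ideal <- rep(p$prebleach_level, n_frames)
  post <- bleach_idx:n_frames
  ideal[post] <- p$prebleach_level *
    (p$bleach_depth + p$mobile_fraction_true * (1 - p$bleach_depth) *
       (1 - 2^(-(times[post] - t_b) / p$t_half_true)))
  decay <- 1 - p$acq_bleach_slope * times
  if (any(decay <= 0)) stop("acq_bleach_slope drives the signal negative in-window")
  with_seed(p$seed, {
    traces <- lapply(seq_len(p$n_worms), function(w) {
      frap_trace(
        worm_id = sprintf("sim_%03d", w), group = "sim",
        times = times,
        bleach_roi = ideal * decay + stats::rnorm(n_frames, 0, p$noise_sd),
        reference_roi = p$prebleach_level * decay +
          stats::rnorm(n_frames, 0, p$noise_sd)
      )
    })
    truth <- data.frame(
      worm_id = vapply(traces, function(tr) tr$worm_id, ""),
      t_half = p$t_half_true,
      mobile_fraction = p$mobile_fraction_true,
      stringsAsFactors = FALSE
    )
    list(traces = traces, truth = truth)
  })
}

#' Simulation parameters for mosaic cohorts
#'
#' @param loss_prob_per_division Probability that a daughter cell fails to
#'   inherit the array at each division.
#' @param call_noise_rate Probability that a tissue call is corrupted by one
#'   ordinal grade.
#' @param n_worms Number of worms.
#' @param seed RNG seed.
#' @return A validated list of class `mosaic_sim_params`.
#' @export
mosaic_sim_params <- function(loss_prob_per_division = 0.05,
                              call_noise_rate = 0, n_worms = 20, seed = 1) {
  stopifnot(loss_prob_per_division >= 0, loss_prob_per_division <= 1,
            call_noise_rate >= 0, call_noise_rate <= 1, n_worms >= 1)
  structure(list(loss_prob_per_division = loss_prob_per_division,
                 call_noise_rate = call_noise_rate,
                 n_worms = as.integer(n_worms), seed = as.integer(seed)),
            class = "mosaic_sim_params")
}

# one Dollo realization: loss happens independently on each tree edge and is
# heritable and irreversible; returns the antichain of maximal lost nodes
simulate_dollo_losses <- function(tree, loss_prob) {
  lost <- stats::setNames(rep(FALSE, length(tree$nodes)), tree$nodes)
  # parent-before-child order: walk nodes by depth
  depth <- vapply(tree$nodes, function(nd) sum(tree$anc[, nd]), 0)
  for (nd in tree$nodes[order(depth)]) {
    par <- tree$parent[[nd]]
    if (is.na(par)) next
    lost[nd] <- lost[par] || (stats::runif(1) < loss_prob)
  }
  tree$nodes[vapply(tree$nodes, function(nd) {
    par <- tree$parent[[nd]]
    lost[nd] && (is.na(par) || !lost[par])
  }, TRUE)]
}

corrupt_call <- function(call, rate) {
  if (stats::runif(1) >= rate) return(call)
  r <- call_rank(call)
  shift <- if (r == 0L) 1L else if (r == 3L) -1L
           else sample(c(-1L, 1L), 1)
  rank_to_call(r + shift)
}

#' Generate a synthetic mosaic cohort with known loss events
#'
#' Array loss is simulated independently at every cell division with the
#' given probability and inherited irreversibly (a Dollo process); tissue
#' calls are derived with [predict_calls()] and then optionally corrupted by
#' one ordinal grade per call at the noise rate.
#'
#' @param tree A [lineage_tree()].
#' @param tissue_map Named list of [tissue_def()]s.
#' @param params A [mosaic_sim_params()].
#' @return List with `observations` (named list: worm -> named call vector)
#'   and `truth` (named list: worm -> loss antichain).
#' @export
gen_mosaic_cohort <- function(tree = default_tree(),
                              tissue_map = default_tissue_map(),
                              params = mosaic_sim_params()) {
  stopifnot(inherits(params, "mosaic_sim_params"))
  with_seed(params$seed, {
    obs <- list()
    truth <- list()
    for (w in seq_len(params$n_worms)) {
      id <- sprintf("simworm_%03d", w)
      events <- simulate_dollo_losses(tree, params$loss_prob_per_division)
      calls <- predict_calls(events, tissue_map, tree)
      if (params$call_noise_rate > 0) {
        calls[] <- vapply(calls, corrupt_call, "", rate = params$call_noise_rate)
      }
      obs[[id]] <- calls
      truth[[id]] <- events
    }
    list(observations = obs, truth = truth)
  })
}

#' Default fatty-acid composition baseline
#'
#' A realistic resting fatty-acid profile (mol% per carbon:double-bond bin)
#' for the two major phospholipid classes, dominated by 18:1 and the C20
#' polyunsaturates with a larger saturated share among the PEs. Each class
#' sums to 100.
#'
#' @return Data frame with `lipid_class`, `carbons`, `double_bonds`,
#'   `mol_percent`.
#' @export
default_lipid_baseline <- function() {
  pc <- data.frame(
    lipid_class = "PC",
    carbons = c(14, 16, 16, 18, 18, 18, 18, 20, 20, 20),
    double_bonds = c(0, 0, 1, 0, 1, 2, 3, 3, 4, 5),
    mol_percent = c(2, 6, 4, 8, 25, 12, 6, 7, 10, 20)
  )
  pe <- data.frame(
    lipid_class = "PE",
    carbons = c(16, 16, 18, 18, 18, 18, 20, 20, 20),
    double_bonds = c(0, 1, 0, 1, 2, 3, 3, 4, 5),
    mol_percent = c(10, 4, 15, 18, 10, 5, 8, 12, 18)
  )
  rbind(pc, pe)
}

#' Simulation parameters for lipid composition profiles
#'
#' @param baseline Baseline mol% per (class, carbons, double_bonds) bin;
#'   must sum to 100 within each class.
#' @param condition_effect Named numeric vector: additive shift of the SFA
#'   (double_bonds = 0) mol% share per condition.
#' @param dispersion Dirichlet concentration parameter (> 0); larger values
#'   concentrate samples around the baseline.
#' @param n_per_group Samples per condition.
#' @param seed RNG seed.
#' @return A validated list of class `lipid_sim_params`.
#' @export
lipid_sim_params <- function(baseline = default_lipid_baseline(),
                             condition_effect = c(control = 0, glucose = 10),
                             dispersion = 200, n_per_group = 10, seed = 1) {
  stopifnot(dispersion > 0, n_per_group >= 1,
            !is.null(names(condition_effect)))
  sums <- tapply(baseline$mol_percent, baseline$lipid_class, sum)
  if (any(abs(sums - 100) > 1e-6)) {
    stop("baseline mol% must sum to 100 within each class")
  }
  structure(list(baseline = baseline, condition_effect = condition_effect,
                 dispersion = dispersion, n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "lipid_sim_params")
}

shift_sfa <- function(baseline, effect) {
  out <- baseline
  for (cl in unique(out$lipid_class)) {
    idx <- out$lipid_class == cl
    sfa <- out$double_bonds[idx] == 0
    sfa0 <- sum(out$mol_percent[idx][sfa])
    target <- min(max(sfa0 + effect, 0.1), 99.9)
    scale_sfa <- target / sfa0
    scale_rest <- (100 - target) / (100 - sfa0)
    mp <- out$mol_percent[idx]
    mp[sfa] <- mp[sfa] * scale_sfa
    mp[!sfa] <- mp[!sfa] * scale_rest
    out$mol_percent[idx] <- mp
  }
  out
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate synthetic lipid composition profiles
#'
#' Per sample, bin proportions are drawn class-wise from a Dirichlet
#' distribution centred on the baseline composition, with the baseline SFA
#' share first shifted additively by the condition effect. Each class sums to
#' 100 mol% by construction.
#'
#' @param params A [lipid_sim_params()].
#' @return Data frame in mol% dialect with `sample_id` and `condition`.
#' @export
gen_lipid_profiles <- function(params = lipid_sim_params()) {
  stopifnot(inherits(params, "lipid_sim_params"))
  with_seed(params$seed, {
    rows <- list()
    for (cond in names(params$condition_effect)) {
      centre <- shift_sfa(params$baseline, params$condition_effect[[cond]])
      for (r in seq_len(params$n_per_group)) {
        smp <- centre
        smp$sample_id <- sprintf("%s_%02d", cond, r)
        smp$condition <- cond
        for (cl in unique(smp$lipid_class)) {
          idx <- smp$lipid_class == cl
          alpha <- params$dispersion * centre$mol_percent[idx] / 100
          smp$mol_percent[idx] <- 100 * rdirichlet_one(alpha)
        }
        rows[[length(rows) + 1L]] <- smp
      }
    }
    out <- do.call(rbind, rows)
    out <- out[c("sample_id", "condition", "lipid_class", "carbons",
                 "double_bonds", "mol_percent")]
    rownames(out) <- NULL
    attr(out, "mode") <- "mol_percent"
    out
  })
}

#' Generate a two-group worm-length assay
#'
#' Gaussian samples emulating plate-level length measurements of 20-25 worms
#' per group (defaults reproduce the recorded scale of ~0.995 +/- 0.058 mm
#' adults); the second group's mean is shifted by `effect_mm`.
#'
#' @param mean_mm Mean length of the reference group (mm).
#' @param sd_mm Standard deviation (mm, >= 0).
#' @param effect_mm Additive shift of the second group's mean (mm).
#' @param n_per_group Worms per group (>= 2).
#' @param seed RNG seed.
#' @return List with numeric vectors `a` (reference) and `b` (shifted).
#' @export
gen_length_assay <- function(mean_mm = 0.995, sd_mm = 0.058, effect_mm = 0,
                             n_per_group = 20, seed = 1) {
  stopifnot(sd_mm >= 0, n_per_group >= 2)
  with_seed(seed, {
    list(a = stats::rnorm(n_per_group, mean_mm, sd_mm),
         b = stats::rnorm(n_per_group, mean_mm + effect_mm, sd_mm))
  })
}
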