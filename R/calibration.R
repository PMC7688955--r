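#' Calibration parameter bounds
#'
#' Box bounds for the global parameters. The chemotherapy decay rates are
#' bounded by the configured literature ranges for each drug's terminal
#' elimination half-life, `beta in [ln 2 / t_half_max, ln 2 / t_half_min]`;
#' the diffusion coefficient is capped by the explicit-scheme stability
#' limit at the nominal time step on the calibration grid; efficacies and
#' the targeted-therapy effectiveness are capped by configuration
#' (`mu in [0, 1]` by default, so the growth modulation stays >= -1).
#'
#' @param config a [study_config()] with `thalf_drug1`, `thalf_drug2`
#'   (days), `alpha_cap`, `k_cap`, `mu_cap`.
#' @param spacing voxel spacing of the calibration grid (mm).
#' @return list of `[lo, hi]` bounds per parameter (`d0`, `alpha1`,
#'   `alpha2`, `beta1`, `beta2`, `mu`, `k`).
#' @export
default_bounds <- function(config, spacing) {
  th1 <- config$thalf_drug1
  th2 <- config$thalf_drug2
  if (is.null(th1) || is.null(th2))
    stop("half-life ranges 'thalf_drug1'/'thalf_drug2' missing from config")
  if (any(c(th1, th2) <= 0) || th1[1] > th1[2] || th2[1] > th2[2])
    stop("half-life ranges must be positive and ordered [min, max]")
  d_cap <- 1 / (2 * config$dt * sum(1 / spacing^2))
  list(d0 = c(0, d_cap),
       alpha1 = c(0, config$alpha_cap), alpha2 = c(0, config$alpha_cap),
       beta1 = log(2) / rev(th1), beta2 = log(2) / rev(th2),
       mu = c(0, config$mu_cap),
       k = c(if (is.null(config$k_lo)) 0 else config$k_lo, config$k_cap))
}

#' Assemble a calibration problem
#'
#' Down-samples the measured data by the paper-prescribed factor (4 by
#' default) onto the model grid: cellularity in block-sum mode with the
#' carrying capacity scaled by `factor^3` (cell conservation keeps
#' `N / theta` consistent), drug maps in block-mean mode re-normalized to
#' maximum 1, and tissue labels by block majority. The voxelwise
#' proliferation rate is defined on the union of the two scan ROIs dilated
#' by 2 voxels; residuals are evaluated on the (undilated) union ROI, with
#' voxels present in only one scan contributing a measured count of 0 at
#' the missing time.
#'
#' @param scan1,scan2 measured [cellularity_map()]s on the imaging grid.
#' @param chemo_map_scan1,chemo_map_scan2,trastuzumab_map normalized drug
#'   maps on the imaging grid ([image_volume()]).
#' @param domain a [breast_domain()] on the imaging grid.
#' @param schedule a [treatment_schedule()].
#' @param config a [study_config()].
#' @param factor down-sampling factor.
#' @return a `calibration_problem`.
#' @export
calibration_problem <- function(scan1, scan2, chemo_map_scan1,
                                chemo_map_scan2, trastuzumab_map, domain,
                                schedule, config = study_config(),
                                factor = 4L) {
  f <- as.integer(factor)
  sp <- scan1$spacing
  sp_ds <- sp * f
  theta_ds <- scan1$theta * f^3
  dsn <- function(m) downsample_by_factor(image_volume(m$counts, sp), f, "sum")
  n1v <- dsn(scan1); n2v <- dsn(scan2)
  roi1 <- n1v$values > 0
  roi2 <- n2v$values > 0
  n1 <- cellularity_map(pmin(n1v$values, theta_ds), theta_ds, roi1, sp_ds)
  n2 <- cellularity_map(pmin(n2v$values, theta_ds), theta_ds, roi2, sp_ds)
  renorm <- function(v) volume_like(v$values / max(v$values), v)
  dsm <- function(m) renorm(downsample_by_factor(m, f, "mean"))
  labels_ds <- downsample_labels(domain$tissue_labels, f)
  domain_ds <- breast_domain(labels_ds > 0L, labels_ds)
  union_roi <- (roi1 | roi2) & domain_ds$mask
  support <- dilate_mask(roi1 | roi2, 2L) & domain_ds$mask
  mech_op <- elastic_operator(material_field(domain_ds, config), domain_ds,
                              sp_ds)
  structure(list(scan1 = n1, scan2 = n2,
                 drug_maps = drug_field_set(dsm(chemo_map_scan1),
                                            dsm(chemo_map_scan2),
                                            dsm(trastuzumab_map), schedule),
                 domain = domain_ds, schedule = schedule,
                 union_roi = union_roi, k_support = support,
                 mech_op = mech_op,
                 theta = theta_ds, spacing = sp_ds, factor = f,
                 config = config,
                 bounds = default_bounds(config, sp_ds)),
            class = "calibration_problem")
}

# Pack/unpack the global parameter vector; the mri variant has no mu.
global_names <- function(variant)
  c("d0", "alpha1", "alpha2", "beta1", "beta2",
    if (variant == "pet_mri") "mu")

params_from_vector <- function(pg, k_map, problem, variant) {
  nm <- global_names(variant)
  v <- stats::setNames(as.numeric(pg), nm)
  model_parameters(d0 = v[["d0"]], k_map = k_map, theta = problem$theta,
                   alpha1 = v[["alpha1"]], alpha2 = v[["alpha2"]],
                   beta1 = v[["beta1"]], beta2 = v[["beta2"]],
                   mu = if (variant == "pet_mri") v[["mu"]] else 0)
}

#' Calibration objective: sum of squared errors at scan 2
#'
#' Simulates from the scan-1 state to the scan-2 time and returns the
#' residuals (simulated minus measured cell counts) over the union-ROI
#' evaluation support together with their sum of squares. A numerically
#' unstable simulation returns a large penalty with `unstable = TRUE`
#' rather than erroring, so the optimizer can retreat.
#'
#' @param params a [model_parameters()] on the problem grid.
#' @param problem a [calibration_problem()].
#' @param variant `"pet_mri"` or `"mri"`.
#' @return list `sse`, `residuals`, `unstable`.
#' @export
objective_sse <- function(params, problem, variant = c("pet_mri", "mri")) {
  variant <- match.arg(variant)
  sim <- tryCatch(
    simulate_tumor(problem$scan1, 0, problem$schedule$scan2_time, params,
                   problem$drug_maps, problem$domain, variant = variant,
                   config = problem$config, mech_op = problem$mech_op),
    error = function(e) NULL)
  if (is.null(sim)) {
    nr <- sum(problem$union_roi)
    return(list(sse = 1e30, residuals = rep(1e15, nr), unstable = TRUE))
  }
  r <- (sim$final$counts - problem$scan2$counts)[problem$union_roi]
  list(sse = sum(r * r), residuals = r, unstable = FALSE)
}

# Bounded Levenberg-Marquardt with forward-difference Jacobian and
# projection onto the box. Small and dense: intended for a handful of
# global parameters.
lm_bounded <- function(resid_fn, p0, lower, upper, max_iter = 30,
                       ftol = 1e-6, lambda0 = 1e-2, fd_rel = 1e-4) {
  p <- pmin(pmax(p0, lower), upper)
  fd_scale <- pmax(0.05 * (upper - lower), 1e-6)
  fd_scale[!is.finite(fd_scale)] <- 1e-3
  r <- resid_fn(p)
  sse <- sum(r * r)
  lam <- lambda0
  n_eval <- 1L
  n_small <- 0L
  for (it in seq_len(max_iter)) {
    J <- matrix(0, length(r), length(p))
    for (j in seq_along(p)) {
      h <- fd_rel * max(abs(p[j]), fd_scale[j])
      if (p[j] + h > upper[j]) h <- -h
      pj <- p; pj[j] <- pj[j] + h
      J[, j] <- (resid_fn(pj) - r) / h
      n_eval <- n_eval + 1L
    }
    # scale columns to comparable units, then take a truncated-SVD damped
    # step: directions the data barely constrains (tiny singular values)
    # receive no step, so unidentifiable parameter combinations stay where
    # they were initialized instead of drifting along exact-fit ridges
    colsc <- pmax(sqrt(colSums(J^2)), 1e-300)
    Js <- sweep(J, 2, colsc, "/")
    sv <- svd(Js)
    ur <- crossprod(sv$u, r)
    improved <- FALSE
    for (try in 1:8) {
      keep <- sv$d >= 1e-3 * sv$d[1]
      coef <- ifelse(keep, sv$d / (sv$d^2 + lam * sv$d[1]^2), 0)
      step <- -(sv$v %*% (coef * ur)) / colsc
      if (!is.null(step)) {
        p_new <- pmin(pmax(p + as.numeric(step), lower), upper)
        r_new <- resid_fn(p_new)
        n_eval <- n_eval + 1L
        sse_new <- sum(r_new * r_new)
        if (is.finite(sse_new) && sse_new < sse) {
          rel <- (sse - sse_new) / max(sse, 1e-300)
          p <- p_new; r <- r_new; sse <- sse_new
          lam <- max(lam / 3, 1e-12)
          improved <- TRUE
          n_small <- if (rel < ftol) n_small + 1L else 0L
          break
        }
        lam <- lam * 5
      }
      if (improved) break
    }
    if (!improved || n_small >= 2L)
      return(list(p = p, sse = sse, iterations = it,
                  converged = TRUE, n_eval = n_eval))
  }
  list(p = p, sse = sse, iterations = max_iter, converged = FALSE,
       n_eval = n_eval)
}

# Stage-B proliferation-map fit. The scan-2 count at a voxel depends on its
# own k approximately as N2 ~ exp(k T_eff), so the natural Gauss-Newton step
# is taken in log space: k_i <- k_i + damp * log(measured_i / simulated_i)/T,
# a damped fixed-point iteration that is exact for uncoupled exponential
# growth and converges in a handful of simulations. When progress stalls it
# falls back to a full finite-difference Levenberg-Marquardt polish on the
# k vector (one simulation per support voxel per iteration).
fit_k_map <- function(k0, resid_fn, meas, support_idx, union_idx, theta,
                      t_span, lower, upper, max_iter = 12, ftol = 1e-6,
                      polish_iter = 2L, polish_tol = 1e-4) {
  k <- k0
  r <- resid_fn(k)
  sse <- sum(r * r)
  sse_ref <- max(sum(meas^2), 1e-300)
  upd <- match(union_idx, support_idx)   # residual slot -> support slot
  eps0 <- 1e-9 * theta
  eps_mass <- 1e-5 * theta
  for (it in seq_len(max_iter)) {
    simv <- r + meas
    dk_res <- log((meas + eps0) / pmax(simv + eps0, eps0)) / t_span
    # voxels carrying no appreciable mass in either data or simulation hold
    # no information about k; freeze them instead of chasing caps
    dk_res[meas < eps_mass & simv < eps_mass] <- 0
    damp <- 1
    improved <- FALSE
    for (try in 1:6) {
      k_new <- k
      tgt <- support_idx[upd[!is.na(upd)]]
      k_new[tgt] <- pmin(pmax(k_new[tgt] + damp * dk_res[!is.na(upd)],
                              lower), upper)
      r_new <- resid_fn(k_new)
      sse_new <- sum(r_new * r_new)
      if (is.finite(sse_new) && sse_new < sse) {
        rel <- (sse - sse_new) / max(sse, 1e-300)
        k <- k_new; r <- r_new; sse <- sse_new
        improved <- TRUE
        if (rel < ftol)
          return(list(k = k, sse = sse, residuals = r, iterations = it))
        break
      }
      damp <- damp / 2
    }
    if (!improved) break
  }
  if (sse / sse_ref > polish_tol^2 && polish_iter > 0L) {
    fit <- lm_bounded(function(kv) {
      kk <- k
      kk[support_idx] <- kv
      resid_fn(kk)
    }, k[support_idx], rep(lower, length(support_idx)),
       rep(upper, length(support_idx)), max_iter = polish_iter,
       fd_rel = 1e-3)
    if (fit$sse < sse) {
      k[support_idx] <- fit$p
      sse <- fit$sse
      r <- resid_fn(k)
    }
  }
  list(k = k, sse = sse, residuals = r, iterations = max_iter)
}

# Closed-form per-voxel proliferation initialization: invert the logistic
# map between the two scans, ignoring diffusion and therapy.
init_k_logistic <- function(problem) {
  theta <- problem$theta
  T <- problem$schedule$scan2_time
  n1 <- problem$scan1$counts
  n2 <- problem$scan2$counts
  k <- array(0, dim(n1))
  eps <- 1e-6 * theta
  ok <- problem$k_support & n1 > eps & n2 > eps &
    n1 < theta - eps & n2 < theta - eps
  k[ok] <- log((n2[ok] * (theta - n1[ok])) /
                 (n1[ok] * (theta - n2[ok]))) / T
  lo <- problem$bounds$k[1]; hi <- problem$bounds$k[2]
  k[problem$k_support] <- pmin(pmax(k[problem$k_support], lo), hi)
  k[!problem$k_support] <- 0
  k
}

#' Calibrate the model against the two imaging visits
#'
#' Two-stage bounded Levenberg-Marquardt least squares on the model grid:
#' one stage fits the voxelwise proliferation map (log-space Gauss-Newton
#' with an LM polish) and the other the global parameters (`D0`,
#' chemotherapy efficacies and decay rates, and — for the PET/MRI variant —
#' the targeted-therapy effectiveness `mu`; dense LM with finite-difference
#' Jacobian, box bounds by projection). The proliferation map is fitted
#' first by default (`control$stage_order`): it dominates the between-scan
#' change, and fitting globals against a stale map drives them into bounds.
#' Stages alternate until the relative improvement of the sum of squared
#' errors falls below 0.1% or `max_outer` loops, followed by a short joint
#' refinement over all parameters. Deterministic throughout.
#'
#' Identifiability caveat, reported in `$identifiability`: a voxelwise-free
#' proliferation map can reproduce the scan-2 snapshot exactly for a whole
#' manifold of global-parameter values (any sufficiently strong therapy
#' field is absorbed by a compensating map), so fitted global values retain
#' a strong imprint of their initialization; the residual and the map are
#' well determined, the attribution between `k` and the therapy terms is
#' not.
#'
#' @param problem a [calibration_problem()].
#' @param variant `"pet_mri"` (full model) or `"mri"` (targeted term off).
#' @param init optional named list of initial global values (`d0`,
#'   `alpha1`, `alpha2`, `beta1`, `beta2`, `mu`).
#' @param control list: `max_outer` (default 10), `outer_ftol` (1e-3),
#'   `lm_iter` (profiled global-LM iterations per loop), `k_inner` (inner
#'   map refits per profile evaluation), `k_iter` (map iterations per
#'   loop), `k_polish` (final full-Jacobian map polish iterations),
#'   `joint_iter` (joint refinement iterations).
#' @return a `calibration_result`: fitted [model_parameters()], `sse`,
#'   `n_iterations` (outer loops), `converged`, `residual_map`, `sse_trace`.
#' @export
calibrate <- function(problem, variant = c("pet_mri", "mri"), init = NULL,
                      control = list()) {
  variant <- match.arg(variant)
  if (!any(problem$union_roi)) stop("empty union ROI")
  ctl <- utils::modifyList(list(max_outer = 10L, outer_ftol = 1e-3,
                                lm_iter = 25L, k_iter = 12L, k_polish = 2L,
                                k_inner = 5L, joint_iter = 5L,
                                parsimony = TRUE, verbose = FALSE), control)
  b <- problem$bounds
  nm <- global_names(variant)
  defaults <- list(d0 = 1e-3, alpha1 = 0.1, alpha2 = 0.1,
                   beta1 = mean(b$beta1), beta2 = mean(b$beta2), mu = 0.1)
  if (!is.null(init)) defaults[names(init)] <- init
  pg <- unlist(defaults[nm])
  lower <- vapply(nm, function(s) b[[s]][1], numeric(1))
  upper <- vapply(nm, function(s) b[[s]][2], numeric(1))

  k_map <- init_k_logistic(problem)
  support_idx <- which(problem$k_support)

  sse <- Inf
  sse_ref <- sum(problem$scan2$counts[problem$union_roi]^2)
  trace <- numeric(0)
  outer_used <- 0L
  converged <- FALSE
  res_for <- function(pg) function(k) {
    objective_sse(params_from_vector(pg, k, problem, variant),
                  problem, variant)$residuals
  }
  kfit <- function(k0, pg, iters, polish) fit_k_map(
    k0, res_for(pg), meas = problem$scan2$counts[problem$union_roi],
    support_idx = support_idx, union_idx = which(problem$union_roi),
    theta = problem$theta, t_span = problem$schedule$scan2_time,
    lower = b$k[1], upper = b$k[2], max_iter = iters, polish_iter = polish)
  for (loop in seq_len(ctl$max_outer)) {
    outer_used <- loop
    # profiled global fit: every candidate global vector is evaluated with
    # the proliferation map re-fitted to it (a short inner fixed point), so
    # the LM minimizes the profile objective min_k SSE(globals, k) instead
    # of crawling in block-coordinate steps
    fitA <- lm_bounded(function(p) {
      kfit(k_map, p, ctl$k_inner, 0L)$residuals
    }, pg, lower, upper, max_iter = ctl$lm_iter)
    pg <- fitA$p
    fitB <- kfit(k_map, pg, ctl$k_iter, 0L)
    k_map <- fitB$k
    trace <- c(trace, fitB$sse)
    if (isTRUE(ctl$verbose))
      message(sprintf("outer %d: sse %.4g | %s", loop, fitB$sse,
                      paste(sprintf("%.3g", pg), collapse = " ")))
    # converged when the improvement stalls or the fit reaches numerical
    # noise relative to the data (further iterations only drift along the
    # exact-fit ridge without reducing anything meaningful)
    if (fitB$sse < 1e-8 * sse_ref ||
        (is.finite(sse) && (sse - fitB$sse) < ctl$outer_ftol * sse)) {
      sse <- min(sse, fitB$sse)
      converged <- TRUE
      break
    }
    sse <- fitB$sse
  }
  # parsimonious therapy attribution: any sufficiently strong therapy field
  # explains the data exactly (the proliferation map compensates), so the
  # fitted efficacies land path-dependently on that ridge. Walk them back
  # down jointly while the data remain explained: the smallest therapy
  # attribution consistent with the snapshot, which also strips the
  # compensating distortion out of the proliferation map.
  ai <- which(nm %in% c("alpha1", "alpha2"))
  if (isTRUE(ctl$parsimony) && length(ai) && sse < 1e-6 * sse_ref) {
    for (shrink in c(0.95, 0.99)) {
      repeat {
        pg_try <- pg
        pg_try[ai] <- pg_try[ai] * shrink
        fit_try <- kfit(k_map, pg_try, 2L * ctl$k_iter, 0L)
        if (fit_try$sse < 3e-8 * sse_ref) {
          pg <- pg_try
          k_map <- fit_try$k
          sse <- fit_try$sse
          if (isTRUE(ctl$verbose))
            message(sprintf("parsimony: sse %.4g | %s", sse,
                            paste(sprintf("%.3g", pg), collapse = " ")))
        } else break
      }
    }
  }
  if (ctl$k_polish > 0L) {
    fitB <- kfit(k_map, pg, ctl$k_iter, ctl$k_polish)
    if (fitB$sse <= sse) { k_map <- fitB$k; sse <- fitB$sse }
  }
  # joint refinement: the alternating stages can stall against the bounds
  # (globals pinned while the proliferation map compensates); a short joint
  # Levenberg-Marquardt over [globals, k] moves them in concert
  if (ctl$joint_iter > 0L) {
    ng <- length(pg)
    fitJ <- lm_bounded(function(pv) {
      kk <- k_map
      kk[support_idx] <- pv[-seq_len(ng)]
      objective_sse(params_from_vector(pv[seq_len(ng)], kk, problem, variant),
                    problem, variant)$residuals
    }, c(pg, k_map[support_idx]),
       c(lower, rep(b$k[1], length(support_idx))),
       c(upper, rep(b$k[2], length(support_idx))),
       max_iter = ctl$joint_iter, fd_rel = 1e-3)
    if (fitJ$sse < sse || !is.finite(sse)) {
      pg <- fitJ$p[seq_len(ng)]
      k_map[support_idx] <- fitJ$p[-seq_len(ng)]
      sse <- fitJ$sse
      trace <- c(trace, sse)
      if (isTRUE(ctl$verbose))
        message(sprintf("joint: sse %.4g | %s", sse,
                        paste(sprintf("%.3g", pg), collapse = " ")))
    }
  }
  params <- params_from_vector(pg, k_map, problem, variant)
  obj <- objective_sse(params, problem, variant)
  rmap <- array(0, dim(k_map))
  rmap[problem$union_roi] <- obj$residuals
  ident <- identifiability_report(pg, k_map, problem, variant, lower, upper)
  structure(list(params = params, sse = obj$sse,
                 n_iterations = outer_used, converged = converged,
                 residual_map = rmap, sse_trace = trace,
                 identifiability = ident,
                 variant = variant, problem_theta = problem$theta),
            class = "calibration_result")
}

# Condition number and correlation structure of the global-parameter
# Jacobian at the optimum. A huge condition number or |correlation| ~ 1
# between columns means the data cannot separate those parameters (the
# voxelwise proliferation map can absorb global effects exactly, so fitted
# globals retain their initialization along such ridges).
identifiability_report <- function(pg, k_map, problem, variant, lower, upper) {
  nm <- global_names(variant)
  r0 <- objective_sse(params_from_vector(pg, k_map, problem, variant),
                      problem, variant)$residuals
  J <- matrix(0, length(r0), length(pg), dimnames = list(NULL, nm))
  for (j in seq_along(pg)) {
    h <- 1e-3 * max(abs(pg[j]), 0.05 * (upper[j] - lower[j]), 1e-6)
    pj <- pg
    pj[j] <- if (pj[j] + h <= upper[j]) pj[j] + h else pj[j] - h
    rj <- objective_sse(params_from_vector(pj, k_map, problem, variant),
                        problem, variant)$residuals
    J[, j] <- (rj - r0) / (pj[j] - pg[j])
  }
  sv <- svd(J, nu = 0, nv = 0)$d
  cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  cj <- suppressWarnings(stats::cor(J))
  flagged <- character(0)
  if (length(pg) > 1)
    for (a in seq_len(ncol(cj) - 1)) for (b2 in (a + 1):ncol(cj))
      if (is.finite(cj[a, b2]) && abs(cj[a, b2]) > 0.95)
        flagged <- c(flagged, paste0(nm[a], "~", nm[b2]))
  list(condition_number = cond, correlated_pairs = flagged)
}

#' @export
print.calibration_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("<calibration_result> variant %s, sse = %.4g, %d outer loops%s\n",
              x$variant, x$sse, x$n_iterations,
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("  D0 = %.4g mm^2/day; alpha = (%.4g, %.4g) 1/day; beta = (%.4g, %.4g) 1/day; mu = %.4g\n",
              p$d0, p$alpha1, p$alpha2, p$beta1, p$beta2, p$mu))
  if (!is.null(x$identifiability)) {
    cat(sprintf("  Jacobian condition number %.3g%s\n",
                x$identifiability$condition_number,
                if (length(x$identifiability$correlated_pairs))
                  paste0("; correlated: ",
                         paste(x$identifiability$correlated_pairs,
                               collapse = ", "))
                else ""))
  }
  invisible(x)
}
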