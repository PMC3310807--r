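#' Sweep configuration
#'
#' Declares the parameter grids of a structural sweep. Model set A is the
#' homogeneous wall (no lipid), B the constant-lipid plaque, C the calcified
#' plaque with an agglomerate at calcification gap \code{d_cg}.
#'
#' @param model_set one of \code{"A"}, \code{"B"}, \code{"C"}.
#' @param stenosis stenosis grid (default 0.70).
#' @param d_fc cap-thickness grid (mm), used by sets B and C.
#' @param E_lp lipid Young modulus grid (kPa), sets B and C.
#' @param d_cg calcification-gap grid (mm), set C only.
#' @param E_cag agglomerate modulus grid (kPa) or \code{NULL} to keep the
#'   rule-of-mixtures values; set C only.
#' @param P luminal pressure (kPa).
#' @param level mesh level for every solve.
#' @param seed integer seed fixed at the start of a sweep (the pipeline is
#'   deterministic; the seed guards any future jittered grids).
#' @return an object of class \code{sweep_config}.
#' @export
sweep_config <- function(model_set = c("B", "A", "C"),
                         stenosis = 0.70,
                         d_fc = c(0.05, 0.1625, 0.275, 0.3875, 0.5),
                         E_lp = 1,
                         d_cg = NULL,
                         E_cag = NULL,
                         P = 14.6, level = "medium", seed = 1L) {
  model_set <- match.arg(model_set)
  chk <- function(g, nm) {
    if (!is.null(g) && (!length(g) || is.unsorted(g, strictly = TRUE)))
      stop("invalid-parameter: grid '", nm,
           "' must be non-empty and strictly increasing")
  }
  chk(stenosis, "stenosis"); chk(d_fc, "d_fc"); chk(E_lp, "E_lp")
  chk(d_cg, "d_cg"); chk(E_cag, "E_cag")
  if (model_set == "C" && is.null(d_cg)) d_cg <- 0.02
  structure(list(model_set = model_set, stenosis = stenosis, d_fc = d_fc,
                 E_lp = E_lp, d_cg = d_cg, E_cag = E_cag, P = P,
                 level = level, seed = as.integer(seed)),
            class = "sweep_config")
}

#' Rupture criteria
#'
#' @param stress_threshold critical-stress threshold for rupture (kPa),
#'   default 300.
#' @param cap_thickness_threshold thin-cap threshold (mm), default 0.065
#'   (65 micrometres).
#' @return an object of class \code{rupture_criteria}.
#' @export
rupture_criteria <- function(stress_threshold = 300,
                             cap_thickness_threshold = 0.065) {
  if (stress_threshold <= 0 || cap_thickness_threshold <= 0)
    stop("invalid-parameter: rupture thresholds must be positive")
  structure(list(stress_threshold = stress_threshold,
                 cap_thickness_threshold = cap_thickness_threshold),
            class = "rupture_criteria")
}

#' Run a parametric sweep
#'
#' Solves every grid point of the configuration and tabulates the stress
#' summaries with rupture flags. Geometrically infeasible points are skipped
#' with a warning and recorded as infeasible rows.
#'
#' @param cfg a \code{sweep_config}.
#' @param criteria a \code{rupture_criteria}.
#' @return a data frame of class \code{sweep_result}, one row per grid
#'   point: parameters, \code{sigma_cr}, \code{D_max}, \code{sigma_over_P},
#'   global diagnostics, \code{rupture} and \code{thin_cap} flags,
#'   \code{feasible}.
#' @export
run_sweep <- function(cfg, criteria = rupture_criteria()) {
  stopifnot(inherits(cfg, "sweep_config"),
            inherits(criteria, "rupture_criteria"))
  set.seed(cfg$seed)
  grid <- switch(cfg$model_set,
    A = expand.grid(stenosis = cfg$stenosis),
    B = expand.grid(stenosis = cfg$stenosis, d_fc = cfg$d_fc,
                    E_lp = cfg$E_lp),
    C = expand.grid(stenosis = cfg$stenosis, d_fc = cfg$d_fc,
                    E_lp = cfg$E_lp, d_cg = cfg$d_cg,
                    E_cag = if (is.null(cfg$E_cag)) NA_real_ else cfg$E_cag)
  )
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, , drop = FALSE]
    res <- tryCatch({
      spec <- switch(cfg$model_set,
        A = plaque_geometry(g$stenosis, has_lipid = FALSE),
        B = plaque_geometry(g$stenosis, d_fc = g$d_fc),
        C = plaque_geometry(g$stenosis, d_fc = g$d_fc, d_cg = g$d_cg))
      mats <- switch(cfg$model_set,
        A = default_materials(homogeneous = TRUE),
        B = default_materials(E_lp = g$E_lp),
        C = default_materials(E_lp = g$E_lp,
                              E_cag = if (is.na(g$E_cag)) NULL else g$E_cag))
      fit <- solve_model(spec, mats, load_spec(cfg$P), cfg$level)
      s <- fit$summary
      d_fc_i <- if (cfg$model_set == "A") NA_real_ else g$d_fc
      cbind(g, as.data.frame(s),
            rupture = s$sigma_cr > criteria$stress_threshold,
            thin_cap = !is.na(d_fc_i) &
              d_fc_i <= criteria$cap_thickness_threshold,
            feasible = TRUE)
    }, error = function(e) {
      if (!grepl("infeasible-geometry|meshing error", conditionMessage(e)))
        stop(e)
      warning("skipping infeasible grid point ", i, ": ",
              conditionMessage(e), call. = FALSE)
      cbind(g, sigma_cr = NA_real_, D_max = NA_real_,
            sigma_over_P = NA_real_, sigma_max_global = NA_real_,
            D_max_global = NA_real_, P = cfg$P, N = NA_integer_,
            rupture = NA, thin_cap = NA, feasible = FALSE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (!any(out$feasible)) stop("study error: no feasible grid points")
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  attr(out, "criteria") <- criteria
  class(out) <- c("sweep_result", class(out))
  out
}

#' Normalized stress versus stenosis, with and without a lipid pool
#'
#' The homogeneous-wall model (set A) and the constant-lipid model (set B,
#' cap thickness tied to stenosis with the lipid fixed in space) are solved
#' at each stenosis and their peak circumferential stress, normalized by the
#' luminal pressure, is tabulated.
#'
#' @param stenosis stenosis values.
#' @param level mesh level.
#' @param P luminal pressure (kPa).
#' @param E_lp lipid modulus (kPa).
#' @return data frame with \code{stenosis}, \code{d_fc},
#'   \code{sigma_over_P_homogeneous}, \code{sigma_over_P_lipid}.
#' @export
validate_homogeneous_vs_lipid <- function(stenosis = c(0.70, 0.75, 0.80, 0.90),
                                          level = "medium", P = 14.6,
                                          E_lp = 1) {
  rows <- lapply(stenosis, function(s) {
    homog <- solve_model(plaque_geometry(s, has_lipid = FALSE),
                         default_materials(homogeneous = TRUE),
                         load_spec(P), level)$summary
    d_fc <- cap_thickness_from_stenosis(s)
    lip <- solve_model(plaque_geometry(s, d_fc = d_fc),
                       default_materials(E_lp = E_lp),
                       load_spec(P), level)$summary
    data.frame(stenosis = s, d_fc = d_fc,
               sigma_over_P_homogeneous = homog$sigma_over_P,
               sigma_over_P_lipid = lip$sigma_over_P)
  })
  do.call(rbind, rows)
}

#' Locate the rupture-stress crossing along a sweep axis
#'
#' Finds the first pair of grid points bracketing the critical-stress
#' threshold along the given parameter axis and interpolates linearly; the
#' cap deformation at the crossing (the deformation threshold) is
#' interpolated alongside.
#'
#' @param result a \code{sweep_result} whose feasible rows form a 1-D
#'   section along \code{axis} (all other parameters constant).
#' @param criteria a \code{rupture_criteria}.
#' @param axis parameter column name, e.g. \code{"d_cg"}.
#' @return an object of class \code{threshold_result}: \code{crossed},
#'   threshold \code{value} on the axis, \code{D_max_at_crossing}, the
#'   bracketing rows, or a \code{flag} (\code{"stable over range"} /
#'   \code{"exceeds over range"}) when no crossing exists.
#' @export
find_threshold <- function(result, criteria = rupture_criteria(),
                           axis = "d_cg") {
  stopifnot(axis %in% names(result))
  df <- result[result$feasible, , drop = FALSE]
  df <- df[order(df[[axis]]), , drop = FALSE]
  if (nrow(df) < 2)
    stop("insufficient-data: need at least two feasible points along ", axis)
  x <- df[[axis]]; v <- df$sigma_cr; thr <- criteria$stress_threshold
  out <- list(axis = axis, threshold = thr, crossed = FALSE,
              value = NA_real_, D_max_at_crossing = NA_real_, flag = NULL)
  hit <- which(v[-length(v)] <= thr & v[-1] >= thr)
  if (!length(hit)) {
    out$flag <- if (all(v < thr)) "stable over range" else
      if (all(v > thr)) "exceeds over range" else "non-monotone, no crossing"
    class(out) <- "threshold_result"
    return(out)
  }
  i <- hit[1]
  t_loc <- if (v[i + 1] == v[i]) 0 else (thr - v[i]) / (v[i + 1] - v[i])
  out$crossed <- TRUE
  out$value <- x[i] + t_loc * (x[i + 1] - x[i])
  out$D_max_at_crossing <- df$D_max[i] + t_loc * (df$D_max[i + 1] -
                                                    df$D_max[i])
  out$bracket <- df[c(i, i + 1), c(axis, "sigma_cr", "D_max")]
  class(out) <- "threshold_result"
  out
}

#' @exportS3Method base::print
print.threshold_result <- function(x, ...) {
  if (x$crossed)
    cat(sprintf("threshold: sigma_cr = %g kPa crossed at %s = %.4g (D_max %.4g mm)\n",
                x$threshold, x$axis, x$value, x$D_max_at_crossing))
  else
    cat(sprintf("no %g kPa crossing along %s: %s\n",
                x$threshold, x$axis, x$flag))
  invisible(x)
}

#' Vulnerability verdict for one model
#'
#' Rupture risk is declared when the critical stress exceeds the stress
#' threshold; an independent thin-cap flag is raised when the cap is at or
#' below the histological thin-cap threshold.
#'
#' @param summary a \code{stress_summary}.
#' @param spec the model's \code{plaque_geometry}.
#' @param criteria a \code{rupture_criteria}.
#' @return list with \code{verdict} (\code{"rupture-risk"} or
#'   \code{"stable"}), \code{thin_cap}, and the inputs echoed.
#' @export
classify_plaque <- function(summary, spec, criteria = rupture_criteria()) {
  stopifnot(inherits(summary, "stress_summary"),
            inherits(criteria, "rupture_criteria"))
  verdict <- if (summary$sigma_cr > criteria$stress_threshold)
    "rupture-risk" else "stable"
  thin <- isTRUE(spec$has_lipid) &&
    spec$d_fc <= criteria$cap_thickness_threshold
  list(verdict = verdict, thin_cap = thin, sigma_cr = summary$sigma_cr,
       stress_threshold = criteria$stress_threshold,
       cap_thickness_threshold = criteria$cap_thickness_threshold)
}

#' Parametric pressure waveform
#'
#' Two-harmonic template rescaled so the systolic peak matches the stated
#' maximum; only the peak matters for the quasi-static stress envelope of a
#' linear model.
#'
#' @param period cardiac period (s), default 0.8.
#' @param peak systolic peak pressure (mmHg), default 107.
#' @param diastolic diastolic minimum (mmHg), default 70.
#' @param harmonics coefficients of the two cosine harmonics shaping the
#'   pulse.
#' @return an object of class \code{pressure_waveform}; evaluate it with
#'   \code{waveform_pressure}.
#' @export
pressure_waveform <- function(period = 0.8, peak = 107, diastolic = 70,
                              harmonics = c(-1, -0.35)) {
  if (peak <= diastolic || diastolic < 0)
    stop("waveform error: need peak > diastolic >= 0")
  structure(list(period = period, peak = peak, diastolic = diastolic,
                 harmonics = harmonics), class = "pressure_waveform")
}

#' Evaluate a pressure waveform
#'
#' @param w a \code{pressure_waveform}.
#' @param t times (s); the waveform is periodic.
#' @return pressure in mmHg.
#' @export
waveform_pressure <- function(w, t) {
  om <- 2 * pi / w$period
  raw <- function(tt) w$harmonics[1] * cos(om * tt) +
    w$harmonics[2] * cos(2 * om * tt)
  tt <- seq(0, w$period, length.out = 2048)
  rng <- range(raw(tt))
  s <- (raw(t) - rng[1]) / (rng[2] - rng[1])
  w$diastolic + (w$peak - w$diastolic) * s
}

#' Convert mmHg to kPa
#' @param x pressure in mmHg.
#' @return pressure in kPa.
#' @export
mmhg_to_kpa <- function(x) x * 0.1333224

#' Quasi-static pulsatile envelope
#'
#' Under the linear model, stresses and deformations scale with pressure, so
#' a solve at the reference pressure maps through the waveform as
#' \code{sigma_cr(t) = sigma_cr(P_ref) * p(t) / P_ref}.
#'
#' @param waveform a \code{pressure_waveform}, or a function of time
#'   returning pressure in kPa.
#' @param summary a \code{stress_summary} solved at reference pressure
#'   \code{summary$P}.
#' @param times evaluation times (s); default one period at 200 steps.
#' @return data frame with \code{t}, \code{p_kPa}, \code{sigma_cr},
#'   \code{D_max}.
#' @export
pulsatile_envelope <- function(waveform, summary, times = NULL) {
  stopifnot(inherits(summary, "stress_summary"))
  if (summary$P <= 0)
    stop("invalid-parameter: reference summary must be at positive pressure")
  if (inherits(waveform, "pressure_waveform")) {
    if (is.null(times))
      times <- seq(0, waveform$period, length.out = 200)
    p <- mmhg_to_kpa(waveform_pressure(waveform, times))
  } else {
    if (is.null(times)) times <- seq(0, 1, length.out = 200)
    p <- waveform(times)
  }
  if (any(p < 0)) stop("waveform error: negative pressure values")
  sc <- p / summary$P
  data.frame(t = times, p_kPa = p,
             sigma_cr = summary$sigma_cr * sc,
             D_max = summary$D_max * sc)
}
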