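#' Normalized chemical shift perturbation
#'
#' Combines amide proton and nitrogen shift changes into a single normalized
#' perturbation, `sqrt(dH^2 + (n_scale * dN)^2)`. The nitrogen scaling of 0.2
#' compensates for the wider 15N shift range.
#'
#' @param delta_H,delta_N shift changes in ppm (vectorized).
#' @param n_scale nitrogen scaling factor (default 0.2).
#' @return non-negative normalized shift(s) in ppm.
#' @examples
#' csp(0.1, 0)      # 0.1
#' csp(0, 1)        # 0.2
#' @export
csp <- function(delta_H, delta_N, n_scale = 0.2) {
  if (any(!is.finite(delta_H)) || any(!is.finite(delta_N)))
    abort("csp() requires finite shift changes")
  sqrt(delta_H^2 + (n_scale * delta_N)^2)
}

#' One-site binding isotherm for ligand-induced shift changes
#'
#' The quadratic one-to-one fast-exchange isotherm
#' \deqn{\Delta\delta = \Delta\delta_{max}\,\frac{(P_t+L_t+K_d) -
#'   \sqrt{(P_t+L_t+K_d)^2 - 4 P_t L_t}}{2 P_t}}
#' giving the observed shift change at total ligand concentration `lt` for
#' total protein concentration `pt`. The discriminant is clamped at zero to
#' guard against round-off for stoichiometric points.
#'
#' @param lt total ligand concentration(s), mM.
#' @param pt total protein concentration(s), mM (recycled against `lt`).
#' @param kd dissociation constant, mM.
#' @param ddmax maximum (saturation) shift change, ppm.
#' @return predicted shift change(s), ppm.
#' @export
one_site_shift <- function(lt, pt, kd, ddmax) {
  if (any(pt <= 0)) abort("protein concentration must be positive")
  if (kd <= 0) abort("kd must be positive")
  s <- pt + lt + kd
  disc <- pmax(s^2 - 4 * pt * lt, 0)
  ddmax * (s - sqrt(disc)) / (2 * pt)
}

# Validate a peak-list tibble (one or many residue tracks) and return it with
# canonical column order. Columns: residue_id, atom_label, ligand_conc_mM,
# dH_ppm, dN_ppm.
validate_peaks <- function(peaks) {
  need <- c("residue_id", "atom_label", "ligand_conc_mM", "dH_ppm", "dN_ppm")
  missing <- setdiff(need, names(peaks))
  if (length(missing) > 0)
    abort(paste0("peak list is missing column(s): ", paste(missing, collapse = ", ")))
  peaks <- as_tibble(peaks)
  if (any(!is.finite(peaks$dH_ppm)) || any(!is.finite(peaks$dN_ppm)))
    abort("peak list contains non-finite chemical shifts")
  bad <- peaks |>
    group_by(.data$residue_id, .data$atom_label) |>
    summarise(ok = all(diff(.data$ligand_conc_mM) > 0) && n() >= 2,
              .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad) > 0)
    abort(paste0("concentrations must be strictly increasing with >= 2 points; ",
                 "offending residue(s): ",
                 paste(bad$residue_id, collapse = ", ")))
  peaks[, c(need, setdiff(names(peaks), need))]
}

# Expand a protein-concentration schedule (scalar, or one value per titration
# point) to length n.
expand_schedule <- function(protein_conc, n) {
  if (length(protein_conc) == 1) protein_conc <- rep(protein_conc, n)
  if (length(protein_conc) != n)
    abort("protein_conc must be a scalar or one value per titration point")
  if (any(protein_conc <= 0)) abort("protein concentration must be positive at every point")
  protein_conc
}

# Observed normalized shift displacement of each point relative to the first
# point of the track (the reference; a 0 mM apo point when present).
observed_displacement <- function(track, n_scale = 0.2) {
  csp(track$dH_ppm - track$dH_ppm[1], track$dN_ppm - track$dN_ppm[1],
      n_scale = n_scale)
}

#' Fit the one-site isotherm to a single titration track
#'
#' Least-squares fit of apparent `kd` and `ddmax` to the normalized shift
#' displacements of one residue's peak track. Shifts are measured relative to
#' the first point of the track, so a track may either start at 0 mM ligand or
#' at the first titration point (the model then accounts for the reference
#' offset). Residues whose maximal normalized shift stays below `noise_floor`
#' are flagged non-binding and not fitted.
#'
#' The optimizer works on log(kd) with `kd` bounded in `[1e-6, 100]` mM and is
#' initialized from the ligand-excess (Langmuir) approximation.
#'
#' @param track tibble with columns `residue_id`, `atom_label`,
#'   `ligand_conc_mM`, `dH_ppm`, `dN_ppm` for a single residue (>= 4 points).
#' @param protein_conc total protein concentration, mM; a scalar or a
#'   dilution-corrected per-point schedule.
#' @param noise_floor minimum maximal normalized shift (ppm) required to fit.
#' @param n_scale nitrogen scaling used in the normalized shift.
#' @return object of class `titration_fit` with elements `kd` (mM), `ddmax`
#'   (ppm), `kd_err`, `converged`, `nonbinding`, `sse`, and a `data` tibble
#'   with per-point observed/fitted displacements and residuals. Use
#'   [tidy()], [glance()] or [autoplot()] on it.
#' @export
fit_one_site <- function(track, protein_conc, noise_floor = 0.005,
                         n_scale = 0.2) {
  track <- validate_peaks(track)
  if (length(unique(paste(track$residue_id, track$atom_label))) != 1)
    abort("fit_one_site() expects a single residue track; see fit_kd() for tables")
  n <- nrow(track)
  if (n < 4) abort("one-site fitting requires at least 4 titration points")
  pt <- expand_schedule(protein_conc, n)
  lt <- track$ligand_conc_mM
  dd_obs <- observed_displacement(track, n_scale)

  out <- list(
    residue_id = track$residue_id[1], atom_label = track$atom_label[1],
    kd = NA_real_, ddmax = NA_real_, kd_err = NA_real_,
    converged = FALSE, nonbinding = FALSE, sse = NA_real_,
    noise_floor = noise_floor,
    data = tibble(ligand_conc_mM = lt, protein_conc_mM = pt,
                  dd_obs = dd_obs, dd_fit = NA_real_, residual = NA_real_)
  )
  class(out) <- "titration_fit"

  if (max(dd_obs) < noise_floor) {
    out$nonbinding <- TRUE
    return(out)
  }

  # model displacement relative to the reference (first) point
  predict_dd <- function(kd, ddmax) {
    one_site_shift(lt, pt, kd, ddmax) - one_site_shift(lt[1], pt[1], kd, ddmax)
  }
  sse_fun <- function(p) {
    r <- dd_obs - predict_dd(exp(p[1]), p[2])
    sum(r * r)
  }

  # Langmuir-limit initialization: dd ~ ddmax * Lt / (Lt + Kd)
  ddmax0 <- max(dd_obs) * 1.2
  half <- ddmax0 / 2
  i_half <- which.min(abs(dd_obs - half))
  kd0 <- max(lt[i_half], 1e-4)
  starts <- list(c(log(kd0), ddmax0),
                 c(log(max(kd0 / 10, 1e-5)), ddmax0),
                 c(log(min(kd0 * 10, 50)), ddmax0))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, sse_fun, method = "L-BFGS-B",
            lower = c(log(1e-6), 0), upper = c(log(100), 10),
            control = list(maxit = 2000, factr = 1e3)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    warn("one-site fit failed to evaluate; returning non-converged fit")
    return(out)
  }
  kd <- exp(best$par[1]); ddmax <- best$par[2]
  dd_fit <- predict_dd(kd, ddmax)
  out$kd <- kd
  out$ddmax <- ddmax
  out$sse <- best$value
  out$converged <- best$convergence == 0
  if (!out$converged) warn(paste0("one-site fit did not converge for residue ",
                                  out$residue_id))
  # crude standard error from the curvature of the SSE surface in kd
  h <- 1e-4
  d2 <- (sse_fun(best$par + c(h, 0)) - 2 * best$value +
           sse_fun(best$par - c(h, 0))) / h^2
  if (is.finite(d2) && d2 > 0 && n > 2) {
    sigma2 <- best$value / (n - 2)
    out$kd_err <- kd * sqrt(2 * sigma2 / d2)   # delta method from log-kd
  }
  out$data$dd_fit <- dd_fit
  out$data$residual <- dd_obs - dd_fit
  out
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("One-site titration fit - residue", x$residue_id,
      paste0("(", x$atom_label, ")\n"))
  if (x$nonbinding) {
    cat("  flagged non-binding (max shift below noise floor",
        x$noise_floor, "ppm)\n")
  } else {
    cat(sprintf("  Kd = %.4g mM, ddmax = %.4g ppm, SSE = %.3g, converged: %s\n",
                x$kd, x$ddmax, x$sse, x$converged))
  }
  invisible(x)
}

#' @export
tidy.titration_fit <- function(x, ...) {
  tibble(term = c("kd_mM", "ddmax_ppm"),
         estimate = c(x$kd, x$ddmax),
         std.error = c(x$kd_err, NA_real_))
}

#' @export
glance.titration_fit <- function(x, ...) {
  tibble(kd_mM = x$kd, kd_err = x$kd_err, ddmax_ppm = x$ddmax, sse = x$sse,
         n_points = nrow(x$data), converged = x$converged,
         nonbinding = x$nonbinding)
}

#' @export
augment.titration_fit <- function(x, ...) x$data

#' Fit apparent Kd for every residue in a peak list
#'
#' Maps [fit_one_site()] over all `(residue_id, atom_label)` tracks of a peak
#' list and returns one row per track.
#'
#' @inheritParams fit_one_site
#' @param peaks peak-list tibble (see [read_peaks()] for the CSV layout).
#' @return tibble with columns `residue_id`, `atom_label`, `kd_mM`, `kd_err`,
#'   `ddmax_ppm`, `sse`, `max_csp_ppm`, `n_points`, `converged`, `nonbinding`.
#' @export
fit_kd <- function(peaks, protein_conc, noise_floor = 0.005, n_scale = 0.2) {
  peaks <- validate_peaks(peaks)
  peaks |>
    group_by(.data$residue_id, .data$atom_label) |>
    dplyr::group_map(function(tr, key) {
      tr <- dplyr::bind_cols(key, tr)
      f <- fit_one_site(tr, protein_conc, noise_floor, n_scale)
      tibble(residue_id = key$residue_id, atom_label = key$atom_label,
             kd_mM = f$kd, kd_err = f$kd_err, ddmax_ppm = f$ddmax, sse = f$sse,
             max_csp_ppm = max(observed_displacement(tr, n_scale)),
             n_points = nrow(tr), converged = f$converged,
             nonbinding = f$nonbinding)
    }) |>
    bind_rows()
}

#' Detect nonlinear peak migration in titration tracks
#'
#' Quantifies direction changes of a peak trajectory in `(dH, n_scale * dN)`
#' space: for each interior titration point the turn angle between the
#' incoming and outgoing step vectors is computed; a track is flagged
#' nonlinear when any turn angle exceeds `angle_threshold`. The ligand:protein
#' molar ratio at the maximal turn (`turn_ratio`) localizes the direction
#' change, e.g. near 1:1 for sequential two-site binding.
#'
#' @inheritParams fit_kd
#' @param angle_threshold turn angle (degrees) above which a track is called
#'   nonlinear; default 60.
#' @param zero_tol step vectors shorter than this (ppm) are treated as
#'   degenerate; their turn angles are undefined and skipped.
#' @return tibble with one row per track: `residue_id`, `atom_label`,
#'   `max_turn_deg`, `turn_ratio` (Lt/Pt at the maximal turn), `is_nonlinear`,
#'   `n_skipped` (degenerate steps), and a `steps` list-column of per-point
#'   detail (`ligand_conc_mM`, `ratio`, `turn_deg`).
#' @export
detect_migration <- function(peaks, protein_conc, angle_threshold = 60,
                             n_scale = 0.2, zero_tol = 1e-9) {
  peaks <- validate_peaks(peaks)
  peaks |>
    group_by(.data$residue_id, .data$atom_label) |>
    dplyr::group_map(function(tr, key) {
      n <- nrow(tr)
      if (n < 3)
        abort("migration detection requires at least 3 titration points")
      pt <- expand_schedule(protein_conc, n)
      v <- cbind(diff(tr$dH_ppm), n_scale * diff(tr$dN_ppm))
      len <- sqrt(rowSums(v^2))
      turn <- rep(NA_real_, n - 2)
      skipped <- 0L
      for (j in seq_len(n - 2)) {
        if (len[j] < zero_tol || len[j + 1] < zero_tol) {
          skipped <- skipped + 1L
          next
        }
        ct <- sum(v[j, ] * v[j + 1, ]) / (len[j] * len[j + 1])
        turn[j] <- acos(max(-1, min(1, ct))) / DEG
      }
      if (skipped > 0)
        inform(paste0("residue ", key$residue_id, ": ", skipped,
                      " zero-length step(s); turn angle undefined there"))
      ratios <- tr$ligand_conc_mM / pt
      steps <- tibble(ligand_conc_mM = tr$ligand_conc_mM[2:(n - 1)],
                      ratio = ratios[2:(n - 1)], turn_deg = turn)
      has_turn <- any(is.finite(turn))
      imax <- if (has_turn) which.max(turn) else NA_integer_
      tibble(residue_id = key$residue_id, atom_label = key$atom_label,
             max_turn_deg = if (has_turn) turn[imax] else NA_real_,
             turn_ratio = if (has_turn) steps$ratio[imax] else NA_real_,
             is_nonlinear = has_turn && turn[imax] > angle_threshold,
             n_skipped = skipped, steps = list(steps))
    }) |>
    bind_rows()
}

#' @rdname fit_one_site
#' @param object a `titration_fit`.
#' @param ... unused.
#' @method autoplot titration_fit
#' @export
autoplot.titration_fit <- function(object, ...) {
  d <- object$data
  curve <- tibble(
    ligand_conc_mM = seq(min(d$ligand_conc_mM), max(d$ligand_conc_mM),
                         length.out = 200))
  if (!object$nonbinding) {
    ptc <- stats::approx(d$ligand_conc_mM, d$protein_conc_mM,
                         xout = curve$ligand_conc_mM, rule = 2)$y
    curve$dd <- one_site_shift(curve$ligand_conc_mM, ptc, object$kd,
                               object$ddmax) -
      one_site_shift(d$ligand_conc_mM[1], d$protein_conc_mM[1], object$kd,
                     object$ddmax)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ligand_conc_mM,
                                       y = .data$dd_obs)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "total ligand (mM)", y = "normalized shift change (ppm)",
                  title = paste0("Residue ", object$residue_id, " (",
                                 object$atom_label, ")"),
                  subtitle = if (object$nonbinding) "non-binding" else
                    sprintf("Kd = %.3g mM", object$kd)) +
    ggplot2::theme_minimal()
  if (!object$nonbinding)
    p <- p + ggplot2::geom_line(data = curve,
                                ggplot2::aes(y = .data$dd), color = "steelblue")
  p
}

#' Plot peak migration trajectories
#'
#' Peak trajectories in `(dH, dN)` shift space, one panel per residue, with
#' points colored by ligand concentration; the visual signature of nonlinear
#' migration.
#'
#' @inheritParams fit_kd
#' @return a ggplot object.
#' @export
plot_migration <- function(peaks) {
  peaks <- validate_peaks(peaks)
  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$dH_ppm, y = .data$dN_ppm,
                                      color = .data$ligand_conc_mM)) +
    ggplot2::geom_path() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~ residue_id, scales = "free") +
    ggplot2::scale_x_reverse() + ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "1H shift (ppm)", y = "15N shift (ppm)",
                  color = "ligand (mM)") +
    ggplot2::theme_minimal()
}
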