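# Derived clinical per-beat metrics from a simulation trace.

first_crossing <- function(t, x, level, rising = TRUE) {
  dx <- diff(x >= level)
  idx <- if (rising) which(dx == 1) else which(dx == -1)
  if (!length(idx)) return(NA_real_)
  t[idx[1] + 1]
}

#' Per-beat clinical metrics
#'
#' Computes, for each complete beat in a trace, the standard clinical
#' summary: heart rate, end-diastolic and end-systolic volumes, stroke
#' volume and ejection fraction (`EF = (EDV - ESV)/EDV * 100`), cardiac
#' output (net aortic valve flow), stroke work as the pressure-volume loop
#' area (trapezoid quadrature), dp/dt extrema (finite differences), the
#' isovolumic relaxation constant Tau (monoexponential, zero-asymptote fit
#' between the dp/dt minimum and mitral opening), the Tei index
#' `(ICT + IRT)/ET` (ejection bounded by the semilunar open-fraction
#' crossing 0.5; AV-valve closure/reopening marked by inflow cessation
#' and resumption), arterial pressures (aortic root),
#' pulmonary/atrial pressures, effective arterial elastance
#' `Ea = ESP/SV` and the coupling ratio `Ees/Ea`.
#'
#' @param trace A `cvloop_trace` (or any data frame with the trace
#'   column layout).
#' @param beats `"all"`, `"last"`, or integer beat indices.
#' @return Data frame with one row per beat.
#' @export
beat_metrics <- function(trace, beats = "all") {
  bt <- attr(trace, "beats")
  if (is.null(bt) || !nrow(bt)) {
    # synthetic traces: treat the whole record as one beat
    if (!nrow(trace)) stop("beat_metrics: no complete beat in trace")
    bt <- data.frame(t_start = trace$t[1], t_end = trace$t[nrow(trace)],
                     period = diff(range(trace$t)),
                     pes_lv = NA, ves_lv = NA, pes_rv = NA, ves_rv = NA,
                     ees_lv = NA, ees_rv = NA, sw_lv = NA, sw_rv = NA,
                     vo2_lv = NA, vo2_rv = NA, osc = NA)
  }
  # keep beats fully covered by the trace
  tmin <- trace$t[1]; tmax <- trace$t[nrow(trace)]
  bt <- bt[bt$t_start >= tmin - 1e-09 & bt$t_end <= tmax + 1e-09, ,
           drop = FALSE]
  # drop truncated fragments at run-chunk boundaries
  bt <- bt[bt$t_end - bt$t_start > 0.6 * bt$period, , drop = FALSE]
  if (!nrow(bt)) stop("beat_metrics: no complete beat in trace")
  idx <- switch(as.character(beats[1]),
                all = seq_len(nrow(bt)),
                last = nrow(bt),
                as.integer(beats))

  loop_area <- function(p, v) {
    # closed trapezoid integral of p dv around the loop
    n <- length(p)
    -sum(0.5 * (p[-1] + p[-n]) * diff(v))
  }

  rows <- lapply(idx, function(i) {
    sel <- trace$t >= bt$t_start[i] - 1e-09 & trace$t <= bt$t_end[i] + 1e-09
    b <- trace[sel, , drop = FALSE]
    if (nrow(b) < 5) stop("beat_metrics: no complete beat in trace")
    dt <- diff(b$t)
    per <- bt$period[i]
    hr <- 60 / per

    out <- list(beat = i, t_start = bt$t_start[i], t_end = bt$t_end[i],
                hr = hr)
    for (side in c("lv", "rv")) {
      p <- b[[paste0("p_", side)]]; v <- b[[paste0("v_", side)]]
      if (is.null(p) || is.null(v)) next
      edv <- max(v); esv <- min(v)
      sv <- edv - esv
      ef <- if (edv > 0) sv / edv * 100 else 0
      dpdt <- diff(p) / dt
      sw <- loop_area(p, v)
      esp <- bt[[paste0("pes_", side)]][i]
      if (is.na(esp)) esp <- p[which.min(v)[1]]
      ees <- bt[[paste0("ees_", side)]][i]
      ea <- if (sv > 0) esp / sv else NA_real_
      # Tau: monoexponential decay p = p0 exp(-t/tau) fitted from the
      # dp/dt minimum to mitral (tricuspid) opening
      zv <- b[[if (side == "lv") "zeta_mitral" else "zeta_tricuspid"]]
      tau <- NA_real_
      i0 <- which.min(dpdt)
      t_open <- if (!is.null(zv)) first_crossing(b$t, zv, 0.05, TRUE)
                else NA_real_
      if (is.na(t_open) || t_open <= b$t[i0])
        t_open <- b$t[nrow(b)]
      win <- b$t >= b$t[i0] & b$t <= t_open & p > 0.5
      if (sum(win) >= 4) {
        fit <- stats::lm(log(p[win]) ~ b$t[win])
        sl <- stats::coef(fit)[2]
        if (is.finite(sl) && sl < 0) tau <- -1000 / sl
      }
      # Tei index from valve open-fraction crossings: the semilunar
      # open/close crossings of 0.5 anchor ejection; AV-valve closure is
      # the last crossing before ejection and reopening the first after
      # (threshold relaxed when the A-wave does not reach 0.5)
      tei <- NA_real_; ict <- irt <- et <- NA_real_
      za <- b[[if (side == "lv") "zeta_aortic" else "zeta_pulmonic"]]
      if (!is.null(zv) && !is.null(za)) {
        avo <- first_crossing(b$t, za, 0.5, TRUE)
        avc <- first_crossing(b$t, za, 0.5, FALSE)
        mvc <- mvo2 <- NA_real_
        qa <- b[[if (side == "lv") "q_mitral" else "q_tricuspid"]]
        if (!anyNA(c(avo, avc)) && avc > avo && !is.null(qa)) {
          # the AV valve open-fraction drifts slowly through diastasis,
          # so inflow cessation/resumption (5 ml/s) marks closure and
          # reopening instead
          inflow <- qa > 5
          cand <- b$t[inflow & b$t < avo]
          mvc <- if (length(cand)) max(cand) else NA_real_
          cand <- b$t[inflow & b$t > avc]
          mvo2 <- if (length(cand)) min(cand) else NA_real_
        }
        if (!anyNA(c(mvc, avo, avc, mvo2))) {
          ict <- avo - mvc; irt <- mvo2 - avc; et <- avc - avo
          tei <- (ict + irt) / et
        }
      }
      nm <- function(s) paste0(side, "_", s)
      out[[nm("edv")]] <- edv; out[[nm("esv")]] <- esv
      out[[nm("sv")]] <- sv; out[[nm("ef")]] <- ef
      out[[nm("sw")]] <- sw
      out[[nm("dpdt_max")]] <- max(dpdt); out[[nm("dpdt_min")]] <- min(dpdt)
      out[[nm("tau")]] <- tau; out[[nm("tei")]] <- tei
      out[[nm("esp")]] <- esp; out[[nm("ees")]] <- ees
      out[[nm("ea")]] <- ea
      out[[nm("ees_ea")]] <- if (is.na(ees) || is.na(ea)) NA_real_
                             else ees / ea
    }
    if (!is.null(trace$q_aortic))
      out$co <- mean(b$q_aortic) * 60 / 1000
    pa <- if (!is.null(b$p_aortic_root)) b$p_aortic_root else b$p_asc_aorta
    if (!is.null(pa)) {
      out$sap_sys <- max(pa); out$sap_dia <- min(pa)
      out$map <- mean(pa)
    }
    if (!is.null(b$p_pulm_trunk)) {
      out$pap_sys <- max(b$p_pulm_trunk); out$pap_dia <- min(b$p_pulm_trunk)
      out$pap_mean <- mean(b$p_pulm_trunk)
    }
    if (!is.null(b$p_la)) out$lap <- mean(b$p_la)
    if (!is.null(b$p_ra)) out$rap <- mean(b$p_ra)
    if (!is.null(b$v_la)) { out$la_vmin <- min(b$v_la); out$la_vmax <- max(b$v_la) }
    if (!is.null(b$v_ra)) { out$ra_vmin <- min(b$v_ra); out$ra_vmax <- max(b$v_ra) }
    if (!is.null(b$sat_pulm_trunk)) out$svo2 <- mean(b$sat_pulm_trunk)
    if (!is.null(b$sat_asc_aorta)) out$sao2 <- mean(b$sat_asc_aorta)
    as.data.frame(out)
  })
  do.call(rbind, rows)
}
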