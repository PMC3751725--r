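# Solver front end: flattens a validated parameter set into the packed
# arrays the C++ engine consumes, assembles the initial state, and runs
# simulations in chunks delimited by timed parameter events.

# Flatten params into the engine pack (0-based indices).
cv_pack <- function(params) {
  g <- params$global
  comps <- compartment_names(params)
  segs <- params$segments
  nseg <- length(segs)

  ch <- params$chambers
  chv <- function(f) vapply(ch, function(x) as.numeric(x[[f]]), 0)

  # derived segment properties at the reference radius
  vref <- r0 <- i0 <- e0 <- p0 <- lam <- ck <- numeric(nseg)
  grp <- cch <- lin <- integer(nseg)
  for (i in seq_len(nseg)) {
    s <- segs[[i]]
    vref[i] <- pi * s$radius0^2 * s$length * s$count
    r0[i] <- cpp_base_resistance(g$blood_viscosity, s$length, s$radius0,
                                 s$count)
    i0[i] <- cpp_base_inertance(g$blood_density, s$length, s$radius0,
                                s$count)
    e0[i] <- cpp_base_elastance(g$young_modulus, s$thickness, s$radius0,
                                s$length, s$count)
    p0[i] <- s$p0
    lam[i] <- if (is.na(s$lambda)) g$damping_lambda else s$lambda
    grp[i] <- match(s$external_group,
                    c("extrathoracic", "intrathoracic", "pericardial")) - 1L
    cch[i] <- if (is.na(s$compress_chamber)) -1L
              else comp_index(params, s$compress_chamber) - 1L
    ck[i] <- s$compress_k
    lin[i] <- as.integer(isTRUE(s$linear_pv))
  }

  topo <- params$topology
  st <- topo[topo$stateful, , drop = FALSE]
  al <- topo[!topo$stateful, , drop = FALSE]

  va <- params$valves
  vdef <- default_valves()
  vup <- vdn <- integer(4)
  for (k in seq_len(4)) {
    vup[k] <- comp_index(params, vdef[[k]]$up) - 1L
    vdn[k] <- comp_index(params, vdef[[k]]$down) - 1L
  }

  comps <- compartment_names(params)
  sites <- default_shunt_sites()
  areas <- vapply(params$shunts[c("asd", "vsd", "pda")],
                  function(s) s$area, 0)
  sh1 <- sh2 <- integer(3)
  for (k in seq_len(3)) {
    s <- sites[[k]]
    if (all(s %in% comps)) {
      sh1[k] <- comp_index(params, s[1]) - 1L
      sh2[k] <- comp_index(params, s[2]) - 1L
    } else if (areas[k] == 0) {
      sh1[k] <- 0L; sh2[k] <- 0L   # site absent from a reduced topology
    } else {
      stop("shunt site missing from topology: ", paste(s, collapse = "-"))
    }
  }

  ox <- params$oxygen
  ox_idx <- function(name) {
    if (is.null(name) || length(name) == 0 || all(is.na(name))) return(-1L)
    if (!name %in% comps) return(-1L)
    comp_index(params, name) - 1L
  }
  myo <- c(ox_idx(ox$myo_sink_left), ox_idx(ox$myo_sink_right))

  ba <- params$baroreflex
  res_names <- intersect(c("sys_arteriolae", "r_car_arteriolae",
                           "l_car_arteriolae"), names(segs))

  list(
    global = list(dt = g$dt, hb = g$hb, vo2_systemic = g$vo2_systemic,
                  pulm_cap_sat = g$pulm_cap_sat,
                  pulm_shunt_fraction = g$pulm_shunt_fraction,
                  intrathoracic_pressure = g$intrathoracic_pressure,
                  heart_rate = g$heart_rate,
                  hr_alpha_ref = g$hr_alpha_ref,
                  blood_density = g$blood_density,
                  blood_volume = g$blood_volume),
    chambers = list(e_max = chv("e_max"), e_min = chv("e_min"),
                    v0 = chv("v0"), v0_dia = chv("v0_dia"),
                    phi_dia = chv("phi_dia"), alpha1 = chv("alpha1"),
                    alpha2 = chv("alpha2"), n1 = chv("n1"),
                    n2 = chv("n2"), onset = chv("onset"),
                    r_wall = chv("r_wall"), r_outflow = chv("r_outflow"),
                    starling_v_th = chv("starling_v_th"),
                    starling_width = chv("starling_width"),
                    starling_depth = chv("starling_depth"),
                    mass = chv("mass")),
    septum = params$septum,
    pericardium = list(p_min = params$pericardium$p_min,
                       p_scale = params$pericardium$p_scale,
                       v_pc0 = params$pericardium$v_pc0,
                       phi = params$pericardium$phi,
                       myocardial_volume =
                         params$pericardium$myocardial_volume),
    valves = list(up = vup, down = vdn,
                  a_min = vapply(va, function(x) x$a_min, 0),
                  a_max = vapply(va, function(x) x$a_max, 0),
                  k_open = vapply(va, function(x) x$k_open, 0),
                  k_close = vapply(va, function(x) x$k_close, 0)),
    segments = list(v_ref = vref, p0 = p0, e0 = e0, r0 = r0, i0 = i0,
                    lambda = lam, group = grp, compress_chamber = cch,
                    compress_k = ck, linear = lin),
    edges = list(from = comp_index(params, st$from) - 1L,
                 to = comp_index(params, st$to) - 1L,
                 alg_from = comp_index(params, al$from) - 1L,
                 alg_to = comp_index(params, al$to) - 1L),
    shunts = list(c1 = unname(sh1), c2 = unname(sh2),
                  area = unname(areas),
                  gorlin_c = params$shunts$gorlin_c,
                  g = params$shunts$g),
    baroreflex = list(enabled = as.integer(isTRUE(ba$enabled)),
                      sense = max(ox_idx(ba$sense), 0L),
                      setpoint = ba$setpoint, tau = ba$tau,
                      gain_hr = ba$gain_hr, gain_emax = ba$gain_emax,
                      gain_res = ba$gain_res, mult_min = ba$mult_min,
                      mult_max = ba$mult_max,
                      res_segs = comp_index(params, res_names) - 4L - 1L),
    oxygen = list(pva_a = ox$pva_a, pva_b = ox$pva_b, pva_c = ox$pva_c,
                  pulm_cap = ox_idx(ox$pulm_cap),
                  sys_sinks = comp_index(params,
                                         intersect(ox$sys_sinks, comps)) - 1L,
                  myo_sinks = myo),
    ecg = list(w = c(params$ecg$w_lv, params$ecg$w_rv, params$ecg$w_la,
                     params$ecg$w_ra),
               delay = params$ecg$delay),
    solver = list(newton_tol = params$solver$newton_tol,
                  newton_maxit = as.integer(params$solver$newton_maxit),
                  jac_interval = as.integer(params$solver$jac_interval)),
    af = list(enabled = as.integer(isTRUE(params$af$enabled)),
              rr_jitter = params$af$rr_jitter),
    osc_comp = max(ox_idx(params$solver$osc_comp), 4L))
}

#' Assemble the initial simulation state
#'
#' Distributes the configured blood volume over every compartment in
#' proportion to the preset initial volumes (the stored fractions must sum
#' to 1), zeroes all flows, closes all valves and initialises the
#' saturations.  Deterministic for a given configuration.
#'
#' @param params A validated `cvloop_params` object.
#' @return A `cvloop_state` list with the 62-element state vector of the
#'   default topology (`x`), saturations, cycle phase and bookkeeping.
#' @export
cv_assemble <- function(params) {
  cv_validate(params)
  comps <- compartment_names(params)
  iv <- c(vapply(params$chambers, function(c) c$init_volume, 0),
          vapply(params$segments, function(s) s$init_volume, 0))
  frac <- iv / sum(iv)
  if (any(!is.finite(frac)) || abs(sum(frac) - 1) > 1e-06)
    stop("initial volume fractions do not sum to 1")
  # volume matching the preset design total is distributed by the stored
  # fractions; any excess or deficit relative to that total is stressed
  # volume and goes preferentially to compliant compartments (veins),
  # which keeps the stiff capillary beds near their reference pressures
  g <- params$global
  comp <- c(vapply(params$chambers, function(c) 1 / c$e_min, 0),
            vapply(params$segments, function(s) {
              1 / cpp_base_elastance(g$young_modulus, s$thickness,
                                     s$radius0, s$length, s$count)
            }, 0))
  dv <- g$blood_volume - sum(iv)
  vols <- iv + dv * comp / sum(comp)
  if (any(vols <= 0))
    stop("initial volumes not positive after blood volume distribution")
  nq <- sum(params$topology$stateful)
  # start in diastole: atrioventricular valves open, semilunar closed
  zeta0 <- c(1, 0, 1, 0)
  x <- c(vols, rep(0, nq), rep(0, 4), zeta0)
  sat <- c(vapply(params$chambers, function(c) c$init_sat, 0),
           vapply(params$segments, function(s) s$init_sat, 0))
  hr <- params$global$heart_rate
  state <- list(x = unname(x), sat = unname(sat), t = 0, phase = 0,
                period = if (hr > 0) 60 / hr else 1e09,
                beat = 0L, vo2_myo = c(0, 0),
                baro_f = params$baroreflex$setpoint,
                m_hr = 1, m_em = 1, m_res = 1,
                rng = as.numeric(params$af$seed %% 2^31))
  class(state) <- "cvloop_state"
  state
}

trace_colnames <- function(params) {
  comps <- compartment_names(params)
  topo <- params$topology
  st <- topo[topo$stateful, , drop = FALSE]
  al <- topo[!topo$stateful, , drop = FALSE]
  c("t", "beat", "phase", "ecg", "p_thorax", "p_peri", "hr_eff",
    "m_hr", "m_em", "m_res",
    paste0("p_", comps), paste0("v_", comps), paste0("sat_", comps),
    if (nrow(st)) paste0("q_", st$from, "__", st$to) else character(),
    paste0("q_", names(default_valves())),
    paste0("zeta_", names(default_valves())),
    if (nrow(al)) paste0("q_", al$from, "__", al$to) else character(),
    paste0("q_", c("asd", "vsd", "pda")))
}

#' Run a closed-loop simulation
#'
#' Advances the model with implicit Euler at `params$global$dt`
#' (0.25 ms by default), applying timed parameter events and recording a
#' decimated trace of every compartment's pressure, volume, flow and
#' oxygen saturation.
#'
#' @param params A `cvloop_params` object (possibly carrying events from
#'   [apply_scenario()]).
#' @param duration Simulated time, s.
#' @param events Optional data frame `t`, `path`, `value`: at time `t` the
#'   parameter at `path` is set to `value` (merged with any scenario
#'   events attached to `params`).
#' @param record_dt Trace sampling interval, s.
#' @param init Optional `cvloop_state` to continue from (defaults to
#'   [cv_assemble()]).
#' @return A `cvloop_trace`: a data frame of uniformly sampled signals
#'   with attributes `params`, `beats` (per-beat energetics), `diag`
#'   (solver and oxygen-balance diagnostics) and `final_state`.
#' @export
cv_run <- function(params, duration, events = NULL,
                   record_dt = params$solver$record_dt, init = NULL) {
  cv_validate(params)
  if (duration < 0) stop("duration must be non-negative")
  ev <- attr(params, "events")
  if (is.null(ev)) ev <- data.frame(t = numeric(), path = character(),
                                    value = numeric())
  if (!is.null(events)) {
    stopifnot(all(c("t", "path", "value") %in% names(events)))
    ev <- rbind(ev, events[c("t", "path", "value")])
  }
  state <- if (is.null(init)) cv_assemble(params) else init
  cn <- trace_colnames(params)
  if (duration == 0) {
    tr <- as.data.frame(matrix(numeric(0), 0, length(cn),
                               dimnames = list(NULL, cn)))
    return(new_trace(tr, params, NULL, list(), state))
  }

  t0 <- state$t
  ev <- ev[ev$t > t0 & ev$t < t0 + duration, , drop = FALSE]
  # numeric parameter events are ramped linearly over ~1 s (abrupt steps
  # in e.g. vessel radius shock the stiff arteriolar branches); the ramp
  # is resolved as a short staircase of sub-events
  if (nrow(ev)) {
    ramp <- params$solver$event_ramp
    if (is.null(ramp)) ramp <- 1
    if (ramp > 0) {
      pieces <- list()
      nsub <- 8
      for (i in seq_len(nrow(ev))) {
        from <- cv_get(params, ev$path[i])
        if (is.numeric(from) && is.finite(from) && from != ev$value[i]) {
          tt <- ev$t[i] + ramp * seq_len(nsub) / nsub
          pieces[[i]] <- data.frame(
            t = pmin(tt, t0 + duration - 1e-09),
            path = ev$path[i],
            value = from + (ev$value[i] - from) * seq_len(nsub) / nsub)
        } else {
          pieces[[i]] <- ev[i, ]
        }
      }
      ev <- do.call(rbind, pieces)
    }
  }
  bounds <- c(sort(unique(ev$t)), t0 + duration)
  traces <- list(); beats <- list()
  diag <- list(o2_pulm_in = 0, o2_sys_out = 0, o2_myo_out = 0,
               newton_iters = 0, jac_count = 0, substeps = 0,
               sat_clamps = 0, osc_max = 0, steps = 0)
  cur <- params
  for (b in bounds) {
    due <- ev[abs(ev$t - state$t) < 1e-09, , drop = FALSE]
    if (nrow(due))
      for (i in seq_len(nrow(due)))
        cur <- cv_set(cur, due$path[i], due$value[i])
    res <- cpp_advance(cv_pack(cur), unclass(state), b, record_dt)
    state <- res$state
    class(state) <- "cvloop_state"
    traces[[length(traces) + 1]] <- res$trace
    beats[[length(beats) + 1]] <- res$beats
    d <- res$diag
    for (nm in names(diag))
      diag[[nm]] <- if (nm == "osc_max") max(diag[[nm]], d[[nm]])
                    else diag[[nm]] + d[[nm]]
  }
  tr <- do.call(rbind, traces)
  colnames(tr) <- cn
  tr <- as.data.frame(tr)
  # chunk boundaries record the same instant twice; keep the later sample
  tr <- tr[!duplicated(round(tr$t / max(record_dt, 1e-09)),
                       fromLast = TRUE), , drop = FALSE]
  rownames(tr) <- NULL
  bm <- do.call(rbind, beats)
  colnames(bm) <- c("t_start", "t_end", "period", "sw_lv", "sw_rv",
                    "pes_lv", "ves_lv", "pes_rv", "ves_rv", "ees_lv",
                    "ees_rv", "vo2_lv", "vo2_rv", "osc")
  new_trace(tr, params, as.data.frame(bm), diag, state)
}

new_trace <- function(df, params, beats, diag, state) {
  attr(df, "params") <- params
  attr(df, "beats") <- beats
  attr(df, "diag") <- diag
  attr(df, "final_state") <- state
  class(df) <- c("cvloop_trace", "data.frame")
  df
}

#' @export
print.cvloop_trace <- function(x, ...) {
  cat(sprintf("cvloop trace: %d samples, %d signals, t = [%g, %g] s, %s beats\n",
              nrow(x), ncol(x),
              if (nrow(x)) min(x$t) else NA, if (nrow(x)) max(x$t) else NA,
              if (is.null(attr(x, "beats"))) 0 else nrow(attr(x, "beats"))))
  invisible(x)
}

#' External pressure of a compartment group
#'
#' Extrathoracic compartments feel atmospheric (zero) external pressure;
#' intrathoracic compartments feel the intrathoracic pressure; pericardial
#' compartments additionally feel the pericardial pressure at the current
#' total heart volume.
#'
#' @param group One of `"extrathoracic"`, `"intrathoracic"`,
#'   `"pericardial"`.
#' @param p_thorax Intrathoracic pressure, mmHg.
#' @param v_heart_total Total pericardial content volume, ml (required for
#'   the pericardial group).
#' @param pericardium Pericardial parameter list (`p_min`, `p_scale`,
#'   `v_pc0`, `phi`).
#' @return External pressure, mmHg.
#' @export
external_pressure <- function(group, p_thorax = 0, v_heart_total = NULL,
                              pericardium = NULL) {
  switch(group,
    extrathoracic = 0,
    intrathoracic = p_thorax,
    pericardial = {
      if (is.null(v_heart_total) || is.null(pericardium))
        stop("pericardial group requires v_heart_total and pericardium")
      p_thorax + pericardial_pressure(v_heart_total, pericardium$p_min,
                                      pericardium$p_scale,
                                      pericardium$v_pc0, pericardium$phi)
    },
    stop("unknown external-pressure group '", group, "'"))
}

#' Write a trace to CSV
#'
#' One row per sample, one column per signal; the header is the signal
#' name (units: pressures mmHg, volumes ml, flows ml/s, saturations
#' percent, time s).
#'
#' @param trace A `cvloop_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
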