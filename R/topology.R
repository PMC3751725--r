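# Network topology: compartments are the four cardiac chambers plus the
# vascular segments; branches are either stateful (carrying a flow
# differential equation with inertance) or algebraic (quasi-static
# resistive paths through high-resistance, low-inertia beds).  The
# topology travels with the parameter set so alternative trees can be
# simulated; this file only builds the default 26-segment tree.

chamber_names <- c("lv", "rv", "la", "ra")

default_edges <- function() {
  e <- rbind(
    # systemic arterial tree and main systemic path
    c("aortic_root", "asc_aorta",       TRUE),
    c("asc_aorta",   "prox_arch",       TRUE),
    c("prox_arch",   "dist_arch",       TRUE),
    c("prox_arch",   "r_carotid",       TRUE),
    c("dist_arch",   "l_carotid",       TRUE),
    c("dist_arch",   "desc_aorta",      TRUE),
    c("desc_aorta",  "periph_art",      TRUE),
    c("periph_art",  "sys_arteriolae",  TRUE),
    c("sys_arteriolae", "sys_cap",      TRUE),
    c("sys_cap",     "sys_veins",       TRUE),
    c("sys_veins",   "ivc",             TRUE),
    c("ivc",         "ra",              TRUE),
    # carotid / subclavian branches to the superior caval vein
    c("r_carotid",   "r_car_arteriolae", TRUE),
    c("r_car_arteriolae", "r_car_capvein", TRUE),
    c("r_car_capvein", "svc",           FALSE),
    c("l_carotid",   "l_car_arteriolae", TRUE),
    c("l_car_arteriolae", "l_car_capvein", TRUE),
    c("l_car_capvein", "svc",           FALSE),
    c("svc",         "ra",              TRUE),
    # pulmonary circulation
    c("pulm_trunk",  "pu_arteriolae",   TRUE),
    c("pu_arteriolae", "pu_cap",        TRUE),
    c("pu_cap",      "pu_smallveins",   TRUE),
    c("pu_smallveins", "pu_veins",      TRUE),
    c("pu_veins",    "la",              TRUE),
    # coronary circulation, emptying into the right atrium
    c("aortic_root", "l_cor_epi",       TRUE),
    c("l_cor_epi",   "l_cor_micro",     FALSE),
    c("l_cor_micro", "ra",              FALSE),
    c("aortic_root", "r_cor_epi",       TRUE),
    c("r_cor_epi",   "r_cor_micro",     FALSE),
    c("r_cor_micro", "ra",              FALSE)
  )
  data.frame(from = e[, 1], to = e[, 2],
             stateful = as.logical(e[, 3]),
             stringsAsFactors = FALSE)
}

default_valves <- function() {
  list(
    mitral    = list(up = "la", down = "lv"),
    aortic    = list(up = "lv", down = "aortic_root"),
    tricuspid = list(up = "ra", down = "rv"),
    pulmonic  = list(up = "rv", down = "pulm_trunk")
  )
}

default_shunt_sites <- function() {
  list(asd = c("la", "ra"), vsd = c("lv", "rv"),
       pda = c("dist_arch", "pulm_trunk"))
}

compartment_names <- function(params) {
  c(chamber_names, names(params$segments))
}

# index of a compartment name within the state ordering (1-based)
comp_index <- function(params, name) {
  idx <- match(name, compartment_names(params))
  if (any(is.na(idx)))
    stop("unknown compartment: ", paste(name[is.na(idx)], collapse = ", "))
  idx
}
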