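#' Model parameters for the oxidative stress response ODE system
#'
#' Constructs the full parameter set of the OxyR stress-response model.
#' Literature rate constants that are conventionally quoted per second
#' (\code{K_AhpC}, \code{K_KatG}, \code{K_ox}, \code{K_red}) are supplied
#' per second and converted to per-minute (x60) here, so that the whole
#' system is internally consistent in minutes; every other rate is given
#' per minute directly.
#'
#' @param K_AhpC catalytic rate constant of AhpC scavenging, s^-1.
#' @param h_AhpC Michaelis constant of AhpC scavenging, uM.
#' @param K_KatG catalytic rate constant of KatG (catalase), s^-1.
#' @param h_KatG Michaelis constant of KatG, uM.
#' @param KD_AhpC,KD_KatG,KD_GrxA OxyR-promoter dissociation constants, uM.
#' @param Kind_AhpC,Kind_KatG,Kind_GrxA maximal OxyR-dependent induction
#'   rates, uM min^-1.
#' @param R_grxA_basal,R_katG_basal,R_ahpC_basal basal expression rates,
#'   uM min^-1.
#' @param R_H2O2_basal endogenous H2O2 production rate, uM min^-1.
#' @param K_ox OxyR oxidation rate constant, uM^-1 s^-1.
#' @param K_red OxyR reduction rate scale, uM s^-1.
#' @param h_OxyR half-saturation of the OxyR reduction term, uM.
#' @param OxyR_total total OxyR concentration, uM.
#' @param R_influx H2O2 membrane influx rate constant, min^-1.
#' @param g_max unstressed growth (dilution) rate, min^-1.
#' @param K_g half-inhibition intracellular H2O2 concentration of the
#'   growth-inhibition Hill function, uM.  The default was calibrated once
#'   against the model's own intracellular H2O2 scale so that a 100 uM
#'   external step produces near-arrest at the transient spike while growth
#'   recovers at the treated steady state (see the methods vignette).
#' @param n_g Hill exponent of the growth-inhibition function.
#' @param R_n plasmid copy production rate, a.u. min^-1.
#' @param R_constitutive constitutive gene expression rate, a.u. min^-1.
#'
#' @return An object of class \code{oxy_params}: a named list of rates in
#'   per-minute units.
#' @examples
#' p <- oxy_params()
#' p$K_AhpC   # 660 * 60, per minute
#' @export
oxy_params <- function(K_AhpC = 660, h_AhpC = 1.2,
                       K_KatG = 490000, h_KatG = 5900,
                       KD_AhpC = 0.1, KD_KatG = 0.18, KD_GrxA = 0.1,
                       Kind_AhpC = 0.2, Kind_KatG = 0.15, Kind_GrxA = 0.1,
                       R_grxA_basal = 0, R_katG_basal = 0,
                       R_ahpC_basal = 0.01,
                       R_H2O2_basal = 0.02,
                       K_ox = 0.1, K_red = 8, h_OxyR = 2583,
                       OxyR_total = 1, R_influx = 1,
                       g_max = 0.012, K_g = 1.3e-3, n_g = 4,
                       R_n = 0.1, R_constitutive = 0.1) {
  p <- list(
    K_AhpC = K_AhpC * 60, h_AhpC = h_AhpC,
    K_KatG = K_KatG * 60, h_KatG = h_KatG,
    KD_AhpC = KD_AhpC, KD_KatG = KD_KatG, KD_GrxA = KD_GrxA,
    Kind_AhpC = Kind_AhpC, Kind_KatG = Kind_KatG, Kind_GrxA = Kind_GrxA,
    R_grxA_basal = R_grxA_basal, R_katG_basal = R_katG_basal,
    R_ahpC_basal = R_ahpC_basal,
    R_H2O2_basal = R_H2O2_basal,
    K_ox = K_ox * 60, K_red = K_red * 60, h_OxyR = h_OxyR,
    OxyR_total = OxyR_total, R_influx = R_influx,
    g_max = g_max, K_g = K_g, n_g = n_g,
    R_n = R_n, R_constitutive = R_constitutive
  )
  rates <- unlist(p)
  if (any(!is.finite(rates))) stop("all model parameters must be finite")
  if (any(rates < 0)) stop("all model rate constants must be >= 0")
  if (p$OxyR_total <= 0) stop("OxyR_total must be > 0")
  for (nm in c("h_AhpC", "h_KatG", "h_OxyR", "KD_AhpC", "KD_KatG",
               "KD_GrxA", "K_g")) {
    if (p[[nm]] <= 0) stop(sprintf("%s must be > 0", nm))
  }
  if (p$g_max <= 0) stop("g_max must be > 0")
  structure(p, class = "oxy_params")
}

#' @export
print.oxy_params <- function(x, ...) {
  cat("<oxy_params> oxidative stress response model parameters (per-minute units)\n")
  cat(sprintf("  scavenging : K_AhpC=%g h_AhpC=%g | K_KatG=%g h_KatG=%g\n",
              x$K_AhpC, x$h_AhpC, x$K_KatG, x$h_KatG))
  cat(sprintf("  OxyR       : K_ox=%g K_red=%g h_OxyR=%g total=%g\n",
              x$K_ox, x$K_red, x$h_OxyR, x$OxyR_total))
  cat(sprintf("  growth     : g_max=%g K_g=%g n_g=%g\n", x$g_max, x$K_g, x$n_g))
  cat(sprintf("  influx     : R_influx=%g  basal H2O2: %g\n",
              x$R_influx, x$R_H2O2_basal))
  invisible(x)
}

#' Specification of one OxyR-regulated (or constitutive) reporter gene
#'
#' A reporter gene has a basal expression rate and a Michaelis-Menten
#' induction term driven by oxidized OxyR occupancy,
#' \code{occ = OxyR_ox / (OxyR_ox + K_D)}.  A negative \code{K_ind} encodes
#' downregulation; the realized expression rate
#' \code{R_basal + K_ind * occ} is floored at zero (negative production is
#' unphysical).  A gene with \code{K_ind = 0} is constitutive.  If
#' \code{on_plasmid} is set, the induction term is multiplied by the
#' plasmid copy number \code{n}.
#'
#' @param name gene label.
#' @param R_basal basal expression rate, a.u. min^-1.
#' @param K_ind maximal OxyR-dependent induction rate, a.u. min^-1 (signed).
#' @param K_D dissociation constant of oxidized OxyR from this promoter, a.u.
#' @param on_plasmid logical; scale induction with plasmid copy number.
#' @return An object of class \code{gene_spec}.
#' @examples
#' gene_spec("reporter_down", R_basal = 4, K_ind = -3, K_D = 0.1)
#' @export
gene_spec <- function(name, R_basal = 4, K_ind = -3, K_D = 0.1,
                      on_plasmid = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (K_D <= 0) stop("K_D must be > 0")
  if (R_basal < 0) stop("R_basal must be >= 0")
  structure(list(name = name, R_basal = R_basal, K_ind = K_ind,
                 K_D = K_D, on_plasmid = isTRUE(on_plasmid)),
            class = "gene_spec")
}

#' The constitutive control gene
#'
#' Reporter expressed at the model's constitutive rate and not regulated by
#' OxyR, emulating a replication-control promoter used as a growth-dilution
#' control.
#'
#' @param params an \code{\link{oxy_params}} object.
#' @param name gene label.
#' @return A \code{\link{gene_spec}} with \code{K_ind = 0}.
#' @export
constitutive_gene <- function(params, name = "constitutive") {
  gene_spec(name, R_basal = params$R_constitutive, K_ind = 0, K_D = 1)
}

#' Delete the katG catalase gene
#'
#' Returns a parameter set in which katG can be neither basally expressed
#' nor induced, emulating a catalase deletion strain.  Idempotent.
#'
#' @param params an \code{\link{oxy_params}} object.
#' @return Modified \code{oxy_params}.
#' @export
knockout_katG <- function(params) {
  stopifnot(inherits(params, "oxy_params"))
  params$Kind_KatG <- 0
  params$R_katG_basal <- 0
  params
}

as_gene_list <- function(genes) {
  if (inherits(genes, "gene_spec")) genes <- list(genes)
  stopifnot(is.list(genes), length(genes) >= 1L,
            all(vapply(genes, inherits, logical(1), "gene_spec")))
  nms <- vapply(genes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("gene names must be unique")
  names(genes) <- nms
  genes
}
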