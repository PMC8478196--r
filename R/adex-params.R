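#' Adex neuron parameters
#'
#' Constructs the parameter set of an adaptive exponential integrate-and-fire
#' (Adex) neuron with conductance-based synapses. The three presets (`"RS"`,
#' `"FS"`, `"Ch"`) are the regular-spiking, fast-spiking and chattering cell
#' types used throughout the package; `adex_params(cell_type)` returns them
#' with their published constants. `FS2` cells (the highly interconnected
#' interneuron subpopulation of the ING network) share the FS parameters.
#'
#' Units follow the conventions of the field: capacitance in pF, conductances
#' in nS, voltages in mV, times in ms, currents in pA. With these units
#' `dV/dt = pA/pF = mV/ms`, so the membrane equation integrates without
#' conversion factors.
#'
#' @param cell_type `"RS"`, `"FS"` or `"Ch"`; selects the preset.
#' @param v_cut Numerical spike-detection threshold (mV). The default is the
#'   effective threshold `V_th` itself (the literal detection rule). A common
#'   alternative in Adex practice is `V_th + 5 * delta`, which lets the
#'   exponential upstroke develop before detection; pass it explicitly to use
#'   it. Oscillation-frequency results are robust to this choice.
#' @param ... Named overrides of any preset field (e.g. `b = 0`).
#'
#' @return An object of class `adex_params`: a named list with fields
#'   `C` (pF), `g_L` (nS), `E_L` (mV), `V_th` (mV), `delta` (mV), `T_ref` (ms),
#'   `tau_w` (ms), `a` (nS), `b` (pA), `V_rest` (reset potential, mV),
#'   `E_E`, `E_I` (synaptic reversals, mV), `v_cut` (mV) and `cell_type`.
#'
#' @examples
#' rs <- adex_params("RS")
#' rs$V_th   # -40 mV
#' ch <- adex_params("Ch")
#' ch$a      # 80 nS
#' @export
adex_params <- function(cell_type = c("RS", "FS", "Ch"), v_cut = NULL, ...) {
  cell_type <- match.arg(cell_type)
  presets <- list(
    RS = list(V_th = -40,   delta = 2,   T_ref = 5, tau_w = 500, a = 4,  b = 20),
    FS = list(V_th = -47.5, delta = 0.5, T_ref = 5, tau_w = 500, a = 0,  b = 0),
    Ch = list(V_th = -47.5, delta = 0.5, T_ref = 1, tau_w = 50,  a = 80, b = 150)
  )
  p <- c(presets[[cell_type]],
         list(C = 150, g_L = 10,
              E_L = if (cell_type == "Ch") -58 else -65,
              E_E = 0, E_I = -80, V_rest = -65))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown adex_params field(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  p$v_cut <- if (is.null(v_cut)) p$V_th else v_cut
  p$cell_type <- cell_type
  validate_adex_params(p)
  structure(p, class = "adex_params")
}

validate_adex_params <- function(p) {
  stopifnot(p$delta > 0, p$C > 0, p$g_L > 0, p$tau_w > 0, p$T_ref >= 0,
            p$E_I < p$E_L, p$E_L < p$E_E, p$v_cut >= p$V_th)
  invisible(p)
}

#' @export
print.adex_params <- function(x, ...) {
  cat(sprintf("<adex_params: %s>\n", x$cell_type))
  flds <- setdiff(names(x), "cell_type")
  cat(paste(sprintf("  %s = %g", flds, unlist(x[flds])), collapse = "\n"), "\n")
  invisible(x)
}

#' Cell parameters under a threshold interpretation
#'
#' Returns the [adex_params()] preset for a cell type under one of the two
#' readings of the tabulated thresholds. Under `"shifted"` (the network
#' default) the printed threshold is the numerical spike-detection cutoff
#' `V_cut = V_T + 5 * delta` and the exponential take-off threshold is
#' `V_T = -50` mV for every cell type (each printed value equals
#' `-50 + 5 * delta` exactly). Under `"literal"` the printed value is both.
#'
#' @param cell_type `"RS"`, `"FS"` or `"Ch"` (`"FS2"` maps to FS).
#' @param threshold `"shifted"` or `"literal"`.
#' @return An [adex_params()] object.
#' @export
network_cell_params <- function(cell_type, threshold = c("shifted", "literal")) {
  threshold <- match.arg(threshold)
  cell_type <- sub("^FS2$", "FS", cell_type)
  p <- adex_params(cell_type)
  if (threshold == "shifted")
    p <- adex_params(cell_type, V_th = p$V_th - 5 * p$delta, v_cut = p$V_th)
  p
}

#' Synaptic kinetics
#'
#' Decay time constants and per-spike conductance increments of the
#' exponential conductance-based synapses.
#'
#' @param tau_E,tau_I Excitatory/inhibitory decay time constants (ms).
#' @param Q Conductance increment per presynaptic spike (nS); interpreted as
#'   `Q_E` or `Q_I` according to the presynaptic class.
#' @return An object of class `synapse_kinetics`.
#' @export
synapse_kinetics <- function(tau_E = 5, tau_I = 5, Q = 1) {
  stopifnot(tau_E > 0, tau_I > 0, Q >= 0)
  structure(list(tau_E = tau_E, tau_I = tau_I, Q = Q), class = "synapse_kinetics")
}

#' Neuron state
#'
#' Dynamical variables of a single Adex neuron: membrane potential `V` (mV),
#' adaptation current `w` (pA), synaptic conductances `g_E`, `g_I` (nS), and
#' the wall-clock time until which the neuron is refractory (ms).
#'
#' @param V,w,g_E,g_I,refractory_until Initial values.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(V = -65, w = 0, g_E = 0, g_I = 0, refractory_until = -Inf) {
  stopifnot(g_E >= 0, g_I >= 0, is.finite(V), is.finite(w))
  structure(list(V = V, w = w, g_E = g_E, g_I = g_I,
                 refractory_until = refractory_until),
            class = "neuron_state")
}

#' Read cell presets from a YAML or JSON parameter file
#'
#' The file maps cell-type names to named parameter fields, mirroring the
#' published parameter table; see `inst/extdata/cell_presets.yaml` for the
#' reference file shipped with the package.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of [adex_params()] objects.
#' @export
read_cell_presets <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  lapply(setNames(names(raw), names(raw)), function(nm) {
    fields <- raw[[nm]]
    base <- if (nm %in% c("RS", "FS", "Ch", "FS2")) sub("FS2", "FS", nm) else "RS"
    do.call(adex_params, c(list(cell_type = base),
                           fields[setdiff(names(fields), "cell_type")]))
  })
}
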