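# Shared helpers: small network specs and hand-built containers used across
# test files. All fixtures are generated in code; sizes are chosen so the
# whole suite runs in minutes, with the scientific contracts unchanged.

tiny_network <- function(name, factor = 0.04, ...) {
  suppressMessages(scale_network(build_network(name, ...), factor))
}

# A two-neuron chain (RS -> FS, p = 1) driven by injected current only;
# used to probe delay conservation and engine semantics directly.
chain_spec <- function(Q = 5, delay = 1.5) {
  spec <- build_network("PING")
  spec$populations <- data.frame(
    name = c("RS", "FS"), size = c(1L, 1L),
    cell_type = c("RS", "FS"), is_inh = c(FALSE, TRUE))
  spec$synapses <- data.frame(source = "RS", target = "FS", p_connect = 1,
                              Q = Q, delay = delay)
  spec$drive <- drive_spec(n_ext = 0, p_connect = 0, q_ext = 0)
  spec
}

# Hand-built geometry with explicit positions (mm); electrode at origin.
manual_geometry <- function(positions, electrode = c(0, 0)) {
  structure(list(positions = positions, electrode = electrode,
                 arena_side = max(abs(positions)) * 2 + 1),
            class = "lfp_geometry")
}

# Minimal spike container for compute_lfp / spike_phases.
spike_set <- function(neuron, time, is_inh) {
  list(spikes = data.frame(neuron = neuron, time = time), is_inh = is_inh,
       meta = list(duration = if (length(time)) max(time) + 100 else 100))
}

# Phase series built directly (bypassing the filter) for burst-detection
# contracts that need exact control of the envelope.
manual_phase_series <- function(envelope, phase = NULL, fs = 1000) {
  n <- length(envelope)
  structure(list(envelope = envelope,
                 phase = if (is.null(phase)) numeric(n) else phase,
                 fs = fs, time = (seq_len(n) - 1) * 1000 / fs),
            class = "phase_series")
}
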