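#' Neuromorphic energy constants
#'
#' Published per-operation energies for digital neuromorphic hardware:
#' 81 pJ per neuron update per timestep, 1.7 pJ per synaptic spike
#' operation, 120 pJ per plastic-synapse update amortised over `delta_p`
#' timesteps, at 1000 timesteps per second.
#'
#' @param neuron_update_pj,spike_op_pj,synaptic_update_pj energies, pJ.
#' @param delta_p timesteps between synaptic updates.
#' @param steps_per_second wall-clock timestep rate.
#' @return a `cx_energy_constants` list.
#' @export
energy_constants <- function(neuron_update_pj = 81, spike_op_pj = 1.7,
                             synaptic_update_pj = 120, delta_p = 63,
                             steps_per_second = 1000) {
  stopifnot(neuron_update_pj > 0, spike_op_pj > 0, synaptic_update_pj > 0,
            delta_p > 0, steps_per_second > 0)
  structure(list(neuron_update_pj = neuron_update_pj,
                 spike_op_pj = spike_op_pj,
                 synaptic_update_pj = synaptic_update_pj,
                 delta_p = delta_p, steps_per_second = steps_per_second),
            class = "cx_energy_constants")
}

pj_per_step_to_uw <- function(pj, k) pj * 1e-12 * k$steps_per_second * 1e6

#' Neuron-update power component
#'
#' `n_neurons * 81 pJ` per timestep, expressed in microwatts.
#'
#' @param n_neurons neuron count (141 for the full network).
#' @param k [energy_constants()].
#' @return power in uW.
#' @export
neuron_power <- function(n_neurons = 141, k = energy_constants()) {
  stopifnot(n_neurons >= 0)
  pj_per_step_to_uw(n_neurons * k$neuron_update_pj, k)
}

#' Spike-communication power component
#'
#' Time-averaged spike fanout energy:
#' `(1/T) sum_t sum_i y_i(t) * fanout_i * 1.7 pJ` per timestep, in uW,
#' where `fanout_i` is the number of structurally present outgoing
#' synapses of neuron i.
#'
#' @param spike_record binary T x N matrix of spikes, or a list with
#'   `comm_events` (the precomputed double sum) and `n_steps` as returned
#'   in a `cx_run`.
#' @param connectivity_mask binary N x N matrix, entry `[post, pre]` = 1
#'   iff a nonzero weight exists pre -> post (ignored for the precomputed
#'   form).
#' @param k [energy_constants()].
#' @return power in uW.
#' @export
comm_power <- function(spike_record, connectivity_mask = NULL,
                       k = energy_constants()) {
  if (is.list(spike_record)) {
    events_per_step <- spike_record$comm_events / spike_record$n_steps
  } else {
    spike_record <- as.matrix(spike_record)
    if (is.null(connectivity_mask))
      stop("connectivity_mask required with an explicit spike record")
    if (ncol(spike_record) != ncol(connectivity_mask))
      stop("shape mismatch between spike record and connectivity mask")
    fanout <- colSums(connectivity_mask != 0)
    events_per_step <- sum(spike_record %*% fanout) / nrow(spike_record)
  }
  pj_per_step_to_uw(events_per_step * k$spike_op_pj, k)
}

#' Plasticity power component
#'
#' `n_plastic * 120 pJ / delta_p` per timestep, in uW.
#'
#' @param n_plastic plastic synapse count (81 x 18 = 1458 ring-to-E-PG).
#' @param k [energy_constants()].
#' @return power in uW.
#' @export
plasticity_power <- function(n_plastic = 81 * 18, k = energy_constants()) {
  stopifnot(n_plastic >= 0)
  pj_per_step_to_uw(n_plastic * k$synaptic_update_pj / k$delta_p, k)
}

#' Full power report
#'
#' @param run optional `cx_run` providing the spike record for the
#'   communication term; `NULL` reports only the two closed-form terms.
#' @param n_neurons,n_plastic structure counts.
#' @param k [energy_constants()].
#' @return a `cx_power_report` with components and total, uW.
#' @export
power_report <- function(run = NULL, n_neurons = 141, n_plastic = 81 * 18,
                         k = energy_constants()) {
  neuron <- neuron_power(n_neurons, k)
  plast <- plasticity_power(n_plastic, k)
  comm <- if (!is.null(run)) comm_power(run, k = k) else NA_real_
  total <- neuron + plast + if (is.na(comm)) 0 else comm
  structure(list(neuron_uw = neuron, communication_uw = comm,
                 plasticity_uw = plast, total_uw = total),
            class = "cx_power_report")
}

#' Print a power report
#' @param x a `cx_power_report`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
print.cx_power_report <- function(x, ...) {
  cat(sprintf("Neuromorphic power estimate (uW):\n  neuron update  %8.3f\n  communication  %8.3f\n  plasticity     %8.3f\n  total          %8.3f\n",
              x$neuron_uw, x$communication_uw, x$plasticity_uw, x$total_uw))
  invisible(x)
}
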