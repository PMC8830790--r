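#' Construct a stimulus-locked fluorescence trace
#'
#' A uniformly sampled raw GCaMP intensity series with its stimulus epoch.
#' Sampling defaults to 5 frames/s (0.2-s frames). The trace must carry at
#' least 10 s of samples before stimulus onset (the baseline window) and
#' extend past stimulus removal.
#'
#' @param time Sample times in seconds, uniform grid.
#' @param F Raw fluorescence intensity (arbitrary units), same length.
#' @param t_onset,t_removal Stimulus onset and removal times in seconds.
#' @param trace_id Identifier.
#' @param neuron_class One of `"AWB"`, `"ASH"`, `"AVA"`, `"AIB"`, `"RIM"`,
#'   `"other"`.
#' @param genotype,stimulus Labels.
#' @param sampling_tol Tolerance (s) on uniformity of the time grid.
#'
#' @return An object of class `fluor_trace`.
#' @export
fluorescence_trace <- function(time, F, t_onset, t_removal,
                               trace_id = "trace", neuron_class = "other",
                               genotype = "wild_type", stimulus = "odor",
                               sampling_tol = 1e-6) {
  neuron_class <- match.arg(neuron_class, neuron_classes())
  if (length(time) != length(F)) {
    stop("time and F must have the same length", call. = FALSE)
  }
  if (length(time) < 2) stop("trace needs at least 2 samples", call. = FALSE)
  dts <- diff(time)
  dt <- stats::median(dts)
  if (dt <= 0 || any(abs(dts - dt) > sampling_tol)) {
    stop("trace '", trace_id, "' is not uniformly sampled within tolerance",
         call. = FALSE)
  }
  if (!is.finite(t_onset) || !is.finite(t_removal) || t_removal <= t_onset) {
    stop("stimulus epoch invalid: t_removal must exceed t_onset",
         call. = FALSE)
  }
  if (t_onset - time[1] < 10 - sampling_tol) {
    stop("trace '", trace_id,
         "' lacks the 10-s baseline window before stimulus onset",
         call. = FALSE)
  }
  if (time[length(time)] <= t_removal) {
    stop("trace '", trace_id, "' does not extend past stimulus removal",
         call. = FALSE)
  }
  structure(
    list(trace_id = as.character(trace_id), neuron_class = neuron_class,
         genotype = as.character(genotype), stimulus = as.character(stimulus),
         time = as.numeric(time), F = as.numeric(F), dt = dt,
         t_onset = t_onset, t_removal = t_removal),
    class = "fluor_trace"
  )
}

neuron_classes <- function() c("AWB", "ASH", "AVA", "AIB", "RIM", "other")

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf(
    "<fluor_trace '%s'> %s / %s / %s; %d frames @ %.3g s; stimulus [%g, %g] s\n",
    x$trace_id, x$neuron_class, x$genotype, x$stimulus,
    length(x$time), x$dt, x$t_onset, x$t_removal))
  invisible(x)
}

# Indices of frames with time in [from, to) on the trace grid.
# Left-closed, right-open; a small epsilon absorbs grid round-off.
window_idx <- function(time, from, to, dt) {
  eps <- dt * 1e-6
  which(time >= from - eps & time < to - eps)
}

#' Baseline fluorescence
#'
#' The mean raw intensity over the 10-s window immediately before stimulus
#' onset (`[t_onset - 10, t_onset)` on the frame grid).
#'
#' @param trace A [fluorescence_trace()].
#' @return Baseline intensity `F_base`.
#' @export
trace_baseline <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  idx <- window_idx(trace$time, trace$t_onset - 10, trace$t_onset, trace$dt)
  if (length(idx) < round(10 / trace$dt)) {
    stop("insufficient baseline: need 10 s of samples before onset",
         call. = FALSE)
  }
  mean(trace$F[idx])
}

#' Baseline-normalised dF/F trace
#'
#' Converts a raw trace to percent change from baseline:
#' `dff_pct(t) = 100 * (F(t) - F_base) / F_base`, with `F_base` the mean
#' intensity over the 10 s before stimulus onset.
#'
#' @param trace A [fluorescence_trace()].
#' @return An object of class `dff_trace`: the input fields plus `dff_pct`
#'   and `f_base`.
#' @export
dff <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  f_base <- trace_baseline(trace)
  if (f_base <= 0) {
    stop("non-physical baseline: F_base must be positive", call. = FALSE)
  }
  out <- trace
  out$f_base <- f_base
  out$dff_pct <- 100 * (trace$F - f_base) / f_base
  class(out) <- c("dff_trace", "fluor_trace")
  out
}

#' Response windows for ON/OFF quantification
#'
#' @param on_offset,on_duration Window start (s after stimulus onset) and
#'   length for the ON response.
#' @param off_offset,off_duration Likewise after stimulus removal for the
#'   OFF response.
#' @param pre_duration Reference window length before onset/removal (s);
#'   fixed at 10 s in the standard analysis.
#' @return A list of class `response_windows`.
#' @export
response_windows <- function(on_offset = 0, on_duration = 10,
                             off_offset = 0, off_duration = 10,
                             pre_duration = 10) {
  if (on_duration <= 0 || off_duration <= 0 || pre_duration <= 0) {
    stop("window durations must be positive", call. = FALSE)
  }
  if (on_offset < 0 || off_offset < 0) {
    stop("window offsets must be nonnegative", call. = FALSE)
  }
  structure(list(on_offset = on_offset, on_duration = on_duration,
                 off_offset = off_offset, off_duration = off_duration,
                 pre_duration = pre_duration),
            class = "response_windows")
}

#' Default analysis windows per neuron class
#'
#' AWB and ASH (sensory neurons) use 10-s ON and OFF windows; AVA, AIB and
#' RIM (interneurons) use 5-s windows. For AVA, `variant = "ava_late"`
#' selects the alternative ON window, the 2nd 10-s window after onset.
#'
#' @param neuron_class One of `"AWB"`, `"ASH"`, `"AVA"`, `"AIB"`, `"RIM"`.
#' @param variant `"primary"` or `"ava_late"` (AVA only).
#' @return A [response_windows()] object.
#' @export
#' @examples
#' default_windows("AWB")$on_duration          # 10
#' default_windows("AVA", "ava_late")$on_offset  # 10
default_windows <- function(neuron_class,
                            variant = c("primary", "ava_late")) {
  variant <- match.arg(variant)
  if (!neuron_class %in% c("AWB", "ASH", "AVA", "AIB", "RIM")) {
    stop("no default windows for neuron class '", neuron_class,
         "'; supply explicit response_windows()", call. = FALSE)
  }
  if (variant == "ava_late") {
    if (neuron_class != "AVA") {
      stop("variant 'ava_late' applies only to AVA", call. = FALSE)
    }
    return(response_windows(on_offset = 10, on_duration = 10,
                            off_offset = 0, off_duration = 5))
  }
  if (neuron_class %in% c("AWB", "ASH")) {
    response_windows(0, 10, 0, 10)
  } else {
    response_windows(0, 5, 0, 5)
  }
}
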