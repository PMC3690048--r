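# Skin-conductance front end: voltage-divider model and protocol labeling.
#
# The skin resistance Rs sits in series with a fixed R2 across the supply Vcc;
# the ADC digitizes Vo = R2/(Rs + R2) * Vcc after a low-pass filter. Sweating
# under stress lowers Rs, raising Vo, so stress shows as millivolt-scale rises
# of the output.

#' Voltage-divider configuration
#'
#' Defaults: R2 = 890 kOhm, ADC step 0.573 mV, full scale 2.35 V. The supply
#' `Vcc` is board-dependent; the default 1.775 V is back-derived from the
#' divider output printed for a 10 kOhm skin resistance (1.755 V), the more
#' precise of the two available anchors (the 10 MOhm anchor, 0.136 V, implies
#' about 1.664 V; the two are mutually inconsistent, so Vcc is configurable).
#'
#' @param R2 series resistance in ohms.
#' @param Vcc supply voltage in volts.
#' @param adc_resolution ADC step in volts.
#' @param adc_vmax ADC full-scale voltage.
#' @return object of class `divider_config`.
#' @export
divider_config <- function(R2 = 890e3, Vcc = 1.775,
                           adc_resolution = SCR_ADC_STEP_V,
                           adc_vmax = SCR_ADC_VMAX_V) {
  if (R2 <= 0 || Vcc <= 0) stop("R2 and Vcc must be positive")
  structure(list(R2 = R2, Vcc = Vcc, adc_resolution = adc_resolution,
                 adc_vmax = adc_vmax), class = "divider_config")
}

#' Divider output voltage from skin resistance, and its inverse
#'
#' `divider_voltage()` computes `Vo = R2/(Rs + R2) * Vcc`, strictly decreasing
#' in `Rs`; `resistance_from_voltage()` inverts it,
#' `Rs = R2 * (Vcc - Vo)/Vo`, and the two compose to the identity on
#' `(0, Vcc]`.
#'
#' @param Rs skin resistance in ohms (>= 0); vectorized.
#' @param cfg a [divider_config()].
#' @return volts (`divider_voltage`) or ohms (`resistance_from_voltage`).
#' @export
divider_voltage <- function(Rs, cfg = divider_config()) {
  if (any(Rs < 0)) stop("skin resistance must be nonnegative")
  cfg$R2 / (Rs + cfg$R2) * cfg$Vcc
}

#' @rdname divider_voltage
#' @param Vo divider output voltage in volts, in `(0, Vcc]`; vectorized.
#' @export
resistance_from_voltage <- function(Vo, cfg = divider_config()) {
  if (any(Vo <= 0) || any(Vo > cfg$Vcc + 1e-12))
    stop("Vo must lie in (0, Vcc]")
  cfg$R2 * (cfg$Vcc - Vo) / Vo
}

#' Protocol schedules for stress trials
#'
#' A schedule is a set of labeled, non-overlapping time spans; samples outside
#' every span stay unlabeled. `protocol_schedule()` builds one from explicit
#' spans; `stroop_schedule()` labels the task span as stress and a relax
#' window at the beginning (first 55 s), at the end (last 60 s) or a custom
#' span (e.g. 15-55 s for a subject relaxed in neither); `sounds_schedule()`
#' labels a 15 s response span after each sound the subject reacted to as
#' stress and the lead-in/lead-out silence as relax.
#'
#' @param spans data.frame with columns `start_s`, `end_s`, `label`
#'   (`"stress"`/`"relax"`); half-open `[start_s, end_s)`.
#' @param kind protocol kind tag.
#' @return object of class `protocol_schedule`.
#' @export
protocol_schedule <- function(spans, kind = "custom") {
  stopifnot(is.data.frame(spans),
            all(c("start_s", "end_s", "label") %in% names(spans)))
  spans <- spans[order(spans$start_s), , drop = FALSE]
  if (nrow(spans)) {
    if (any(spans$end_s <= spans$start_s)) stop("spans must have end_s > start_s")
    if (!all(spans$label %in% c("stress", "relax")))
      stop("span labels must be 'stress' or 'relax'")
    if (nrow(spans) > 1L &&
        any(spans$start_s[-1L] < spans$end_s[-nrow(spans)] - 1e-12))
      stop("schedule spans overlap (contradictory labels)")
  }
  structure(list(kind = kind, spans = spans), class = "protocol_schedule")
}

#' @rdname protocol_schedule
#' @param test_start,test_end task span in seconds.
#' @param duration_s record duration (needed for `relax = "end"`).
#' @param relax relax-window choice: `"beginning"` (first 55 s), `"end"` (last
#'   60 s) or `"custom"`.
#' @param relax_window numeric `(start_s, end_s)` when `relax = "custom"`.
#' @export
stroop_schedule <- function(test_start, test_end, duration_s,
                            relax = c("beginning", "end", "custom"),
                            relax_window = NULL) {
  relax <- match.arg(relax)
  rw <- switch(relax,
    beginning = c(0, 55),
    end = c(duration_s - 60, duration_s),
    custom = {
      if (is.null(relax_window) || length(relax_window) != 2L)
        stop("relax = 'custom' requires relax_window = c(start_s, end_s)")
      as.numeric(relax_window)
    })
  protocol_schedule(data.frame(
    start_s = c(rw[1], test_start), end_s = c(rw[2], test_end),
    label = c("relax", "stress")), kind = "stroop")
}

#' @rdname protocol_schedule
#' @param sound_onsets_s onset time of each sound (s).
#' @param reactive logical vector: did the subject react to each sound?
#' @param response_s length of the stress span after a reactive sound (15 s).
#' @param lead_in_s,lead_out_s silent relax spans at the start and end (60 s
#'   each by default).
#' @export
sounds_schedule <- function(sound_onsets_s, reactive, duration_s,
                            response_s = 15, lead_in_s = 60, lead_out_s = 60) {
  stopifnot(length(reactive) == length(sound_onsets_s))
  spans <- data.frame(
    start_s = c(0, duration_s - lead_out_s, sound_onsets_s[reactive]),
    end_s = c(lead_in_s, duration_s,
              pmin(sound_onsets_s[reactive] + response_s, duration_s)),
    label = c("relax", "relax", rep("stress", sum(reactive))))
  protocol_schedule(spans, kind = "sounds")
}

#' Label SCR samples by a protocol schedule
#'
#' Every sample falling in a schedule span receives that span's label; samples
#' outside all spans are `"unlabeled"`. An empty schedule leaves the whole
#' record unlabeled.
#'
#' @param scr an [scr_record()].
#' @param schedule a [protocol_schedule()].
#' @return the [scr_record()] with `labels` filled in.
#' @export
label_samples <- function(scr, schedule) {
  stopifnot(inherits(scr, "scr_record"), inherits(schedule, "protocol_schedule"))
  tt <- scr_times(scr)
  labels <- rep("unlabeled", length(tt))
  for (i in seq_len(nrow(schedule$spans))) {
    sp <- schedule$spans[i, ]
    labels[tt >= sp$start_s & tt < sp$end_s] <- sp$label
  }
  scr_record(scr$samples, scr$fs, labels, scr$subject_id)
}
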