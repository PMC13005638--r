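# Approved dosing schedules of the five severe-asthma biologics, and the
# gap/dose-count thresholds of the four-category adherence classification.
# Limits are indexed by the position of the dose opening a gap; benralizumab
# is the only product whose schedule changes phase (Q4W for the first three
# doses, then Q8W), so only it has position-dependent head values.

regimen_table <- list(
  benralizumab = list(
    intervals_head = c(28, 28), interval_rest = 56,
    gap_head = c(56, 84), gap_rest = 112,
    disc_head = c(112, 140), disc_rest = 168,
    min_adherent = 5L, minimal_max = 4L),
  dupilumab = list(
    intervals_head = numeric(), interval_rest = 14,
    gap_head = numeric(), gap_rest = 28,
    disc_head = numeric(), disc_rest = 42,
    min_adherent = 13L, minimal_max = 12L),
  mepolizumab = list(
    intervals_head = numeric(), interval_rest = 28,
    gap_head = numeric(), gap_rest = 56,
    disc_head = numeric(), disc_rest = 84,
    min_adherent = 7L, minimal_max = 6L),
  tezepelumab = list(
    intervals_head = numeric(), interval_rest = 28,
    gap_head = numeric(), gap_rest = 56,
    disc_head = numeric(), disc_rest = 84,
    min_adherent = 7L, minimal_max = 6L),
  omalizumab_q2w = list(
    intervals_head = numeric(), interval_rest = 14,
    gap_head = numeric(), gap_rest = 28,
    disc_head = numeric(), disc_rest = 42,
    min_adherent = 13L, minimal_max = 12L),
  omalizumab_q4w = list(
    intervals_head = numeric(), interval_rest = 28,
    gap_head = numeric(), gap_rest = 56,
    disc_head = numeric(), disc_rest = 84,
    min_adherent = 7L, minimal_max = 6L)
)

#' Dosing regimen of an asthma biologic
#'
#' Returns the expected dose-to-dose interval sequence and the per-phase
#' adherence thresholds for one of the five biologics. Omalizumab is dosed
#' Q2W or Q4W depending on body weight and IgE level, neither of which is in
#' claims; with `omalizumab_schedule = "infer"` (the default) the schedule is
#' inferred per patient from the observed dosing pattern
#' ([infer_omalizumab_regimen()]).
#'
#' @param biologic One of `asthma_biologics`.
#' @param omalizumab_schedule `"infer"`, `"q2w"` or `"q4w"`.
#' @return A `dosing_regimen` object.
#' @examples
#' dosing_regimen("benralizumab")
#' @export
dosing_regimen <- function(biologic,
                           omalizumab_schedule = c("infer", "q2w", "q4w")) {
  biologic <- match.arg(biologic, asthma_biologics)
  if (biologic == "omalizumab") {
    omalizumab_schedule <- match.arg(omalizumab_schedule)
    if (omalizumab_schedule == "infer") {
      out <- regimen_table$omalizumab_q4w
      out$infer <- TRUE
      out$biologic <- "omalizumab"
      out$label <- "omalizumab (schedule inferred)"
      return(structure(out, class = "dosing_regimen"))
    }
    key <- paste0("omalizumab_", omalizumab_schedule)
    out <- regimen_table[[key]]
    out$infer <- FALSE
    out$biologic <- "omalizumab"
    out$label <- key
    return(structure(out, class = "dosing_regimen"))
  }
  out <- regimen_table[[biologic]]
  out$infer <- FALSE
  out$biologic <- biologic
  out$label <- biologic
  structure(out, class = "dosing_regimen")
}

#' @export
print.dosing_regimen <- function(x, ...) {
  ints <- c(x$intervals_head, x$interval_rest)
  cat(sprintf("<dosing_regimen> %s\n", x$label))
  cat(sprintf("  intervals (days): %s then %g repeating\n",
              if (length(x$intervals_head))
                paste(x$intervals_head, collapse = ", ") else "-",
              x$interval_rest))
  cat(sprintf("  adherent: all gaps within window and >= %d doses\n",
              x$min_adherent))
  invisible(x)
}

# expected interval following the dose at 1-based position `pos`
interval_at <- function(regimen, pos) {
  out <- rep(regimen$interval_rest, length(pos))
  nh <- length(regimen$intervals_head)
  if (nh) {
    idx <- which(pos <= nh)
    out[idx] <- regimen$intervals_head[pos[idx]]
  }
  out
}

#' Infer the omalizumab dosing schedule from observed dose dates
#'
#' Claims carry neither body weight nor IgE, so the Q2W vs Q4W omalizumab
#' schedule is inferred from the dosing pattern: Q2W if the median positive
#' inter-dose gap is below 21 days (the midpoint of the two schedules),
#' otherwise Q4W. A single dose defaults to Q4W.
#'
#' @param dose_dates Numeric day offsets of the observed doses (sorted).
#' @return `"q2w"` or `"q4w"`.
#' @examples
#' infer_omalizumab_regimen(c(0, 14, 28, 42)) # "q2w"
#' infer_omalizumab_regimen(c(0, 28, 56))     # "q4w"
#' @export
infer_omalizumab_regimen <- function(dose_dates) {
  if (!length(dose_dates)) abort("cannot infer a schedule from zero doses")
  if (length(dose_dates) == 1L) return("q4w")
  gaps <- diff(sort(dose_dates))
  gaps <- gaps[gaps > 0]
  if (!length(gaps)) return("q4w")
  if (median(gaps) < 21) "q2w" else "q4w"
}

# concrete regimen for a patient: resolves omalizumab schedule inference
resolve_regimen <- function(regimen, dose_dates) {
  if (!isTRUE(regimen$infer)) return(regimen)
  dosing_regimen("omalizumab",
                 omalizumab_schedule = infer_omalizumab_regimen(dose_dates))
}

# list(gap_head, gap_rest, disc_head, disc_rest, min_adherent, minimal_max)
# in the form the C++ kernel expects
regimen_rules <- function(regimen) {
  regimen[c("gap_head", "gap_rest", "disc_head", "disc_rest",
            "min_adherent", "minimal_max")]
}
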