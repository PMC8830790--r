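#' Construct a validated plate-count record
#'
#' One row of a chemotaxis plate assay: the number of worms counted in the
#' odor-side area (`n_toward`), the control-side area (`n_away`) and the
#' middle area (`n_middle`) at the end of the assay, together with the assay
#' type and genotype labels.
#'
#' @param plate_id Identifier for the plate.
#' @param genotype Genotype label (e.g. `"wild_type"`).
#' @param assay_type One of `"attractant"`, `"repellent"`, `"pairing"`.
#' @param n_toward,n_away,n_middle Nonnegative integer worm counts; at least
#'   one worm must be present on the plate.
#'
#' @return A one-row tibble with class `plate_count` prepended.
#' @export
#' @examples
#' plate_count("p1", "wild_type", "attractant", 45, 3, 2)
plate_count <- function(plate_id, genotype, assay_type,
                        n_toward, n_away, n_middle) {
  assay_type <- match.arg(assay_type, assay_types())
  counts <- c(n_toward = n_toward, n_away = n_away, n_middle = n_middle)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("worm counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) < 1) {
    stop("empty plate: n_toward + n_away + n_middle must be >= 1",
         call. = FALSE)
  }
  out <- tibble::tibble(
    plate_id = as.character(plate_id),
    genotype = as.character(genotype),
    assay_type = assay_type,
    n_toward = as.integer(round(n_toward)),
    n_away = as.integer(round(n_away)),
    n_middle = as.integer(round(n_middle))
  )
  class(out) <- c("plate_count", class(out))
  out
}

assay_types <- function() c("attractant", "repellent", "pairing")

#' Choice index of a plate
#'
#' The signed preference score of a two-sided chemotaxis plate:
#' \deqn{CI = (n_{toward} - n_{away}) / N}
#' where `N` is by default the total worm count over all three areas
#' (`denominator = "all"`), or only the worms that left the middle
#' (`denominator = "decided_only"`). A positive value means more worms
#' ended on the odor side; +1 means all worms at the odorant, -1 all worms
#' on the opposite side.
#'
#' @param n_toward,n_away,n_middle Worm counts per area, or a
#'   `plate_count` row passed as `n_toward`.
#' @param denominator `"all"` (default: all three areas) or
#'   `"decided_only"` (exclude middle-area worms).
#'
#' @return Choice index in \[-1, 1\].
#' @export
#' @examples
#' choice_index(45, 3, 2)  # 0.84
choice_index <- function(n_toward, n_away = NULL, n_middle = NULL,
                         denominator = c("all", "decided_only")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(n_toward)) {
    pc <- n_toward
    n_toward <- pc$n_toward
    n_away <- pc$n_away
    n_middle <- pc$n_middle
  }
  if (any(c(n_toward, n_away, n_middle) < 0)) {
    stop("worm counts must be nonnegative", call. = FALSE)
  }
  total <- n_toward + n_away + n_middle
  if (any(total < 1)) {
    stop("empty plate: total worm count must be >= 1", call. = FALSE)
  }
  denom <- if (denominator == "all") total else n_toward + n_away
  if (any(denom < 1)) {
    stop("no worm made a choice; cannot use 'decided_only' denominator",
         call. = FALSE)
  }
  (n_toward - n_away) / denom
}

#' Classify worm choices on a plate
#'
#' Maps the three scored areas onto correct / wrong / no choice for the
#' given assay type and reports the percentages. In the attractant assay
#' the odor side is the correct choice; in the repellent and pairing assays
#' the side opposite the odorant(s) is correct. Worms remaining in the
#' middle made no choice. The incorrect choice is the sum of the wrong
#' choice and no choice.
#'
#' @inheritParams choice_index
#' @param assay_type `"attractant"`, `"repellent"` or `"pairing"`.
#'
#' @return A one-row tibble: `choice_index`, `pct_correct`, `pct_wrong`,
#'   `pct_no_choice`, `pct_incorrect` (percentages of the plate total).
#' @export
#' @examples
#' classify_choices(2, 46, 2, "pairing")  # pct_incorrect = 8
classify_choices <- function(n_toward, n_away = NULL, n_middle = NULL,
                             assay_type = NULL) {
  if (is.data.frame(n_toward)) {
    pc <- n_toward
    if (is.null(assay_type)) assay_type <- pc$assay_type
    n_toward <- pc$n_toward
    n_away <- pc$n_away
    n_middle <- pc$n_middle
  }
  assay_type <- match.arg(assay_type, assay_types())
  total <- n_toward + n_away + n_middle
  if (total < 1) stop("empty plate: total worm count must be >= 1",
                      call. = FALSE)
  n_correct <- if (assay_type == "attractant") n_toward else n_away
  n_wrong <- if (assay_type == "attractant") n_away else n_toward
  tibble::tibble(
    choice_index = choice_index(n_toward, n_away, n_middle),
    pct_correct = 100 * n_correct / total,
    pct_wrong = 100 * n_wrong / total,
    pct_no_choice = 100 * n_middle / total,
    pct_incorrect = 100 * (n_wrong + n_middle) / total
  )
}

#' Integration index
#'
#' How completely a repellent blocks an attractant's effect, as the ratio in
#' percentage of the difference between the pairing and attractant-alone
#' choice indices to the difference between the repellent-alone and
#' attractant-alone choice indices:
#' \deqn{I = 100 (CI_{Pairing} - CI_{Attractant}) /
#'           (CI_{Repellent} - CI_{Attractant})}
#' 0% means the pairing behaves like the attractant alone (no blocking);
#' 100% means it behaves like the repellent alone (complete blocking).
#' Values outside \[0, 100\] are possible and reported unclamped.
#'
#' @param ci_attractant,ci_repellent,ci_pairing Group choice indices.
#' @param tolerance The index is undefined when
#'   `|ci_repellent - ci_attractant| <= tolerance` (the two single-odorant
#'   responses are indistinguishable). Default `1e-6`.
#'
#' @return Integration index in percent.
#' @export
#' @examples
#' integration_index(0.95, -0.95, -0.95)  # 100
integration_index <- function(ci_attractant, ci_repellent, ci_pairing,
                              tolerance = 1e-6) {
  denom <- ci_repellent - ci_attractant
  if (any(abs(denom) <= tolerance)) {
    stop("integration index undefined: attractant and repellent choice ",
         "indices are indistinguishable (|CI_rep - CI_att| <= tolerance)",
         call. = FALSE)
  }
  100 * (ci_pairing - ci_attractant) / denom
}

#' Group-level integration index from plate counts
#'
#' Aggregates three sets of plates (attractant-only, repellent-only,
#' pairing) into an integration index. In `mode = "per_plate"` each pairing
#' plate yields its own index using the group mean attractant and repellent
#' choice indices (matching a per-assay distribution presentation); in
#' `mode = "point"` a single index is computed from the three group means.
#' Both modes return the per-plate values and their median.
#'
#' @param att_plates,rep_plates,pair_plates Data frames of plate counts
#'   (columns `n_toward`, `n_away`, `n_middle`), one row per plate.
#' @param mode `"per_plate"` (default) or `"point"`.
#' @param denominator Passed to [choice_index()].
#' @param tolerance Passed to [integration_index()].
#'
#' @return A list: `integration_index_pct` (the headline value: the median
#'   of per-plate indices, or the point estimate), `per_plate_values`,
#'   `median_pct`, and the three group mean choice indices.
#' @export
group_integration <- function(att_plates, rep_plates, pair_plates,
                              mode = c("per_plate", "point"),
                              denominator = "all", tolerance = 1e-6) {
  mode <- match.arg(mode)
  for (pl in list(att_plates, rep_plates, pair_plates)) {
    if (!is.data.frame(pl) || nrow(pl) == 0) {
      stop("each assay group needs at least one plate", call. = FALSE)
    }
  }
  ci <- function(pl) choice_index(pl$n_toward, pl$n_away, pl$n_middle,
                                  denominator = denominator)
  ci_att <- mean(ci(att_plates))
  ci_rep <- mean(ci(rep_plates))
  ci_pair_plates <- ci(pair_plates)
  per_plate <- vapply(
    ci_pair_plates,
    function(cp) integration_index(ci_att, ci_rep, cp, tolerance = tolerance),
    numeric(1)
  )
  point <- integration_index(ci_att, ci_rep, mean(ci_pair_plates),
                             tolerance = tolerance)
  headline <- if (mode == "per_plate") stats::median(per_plate) else point
  list(
    integration_index_pct = headline,
    per_plate_values = per_plate,
    median_pct = stats::median(per_plate),
    mode = mode,
    ci_attractant = ci_att,
    ci_repellent = ci_rep,
    ci_pairing = mean(ci_pair_plates)
  )
}

#' Score a table of plate counts
#'
#' Vectorised scoring of a plate-count table: appends the choice index and
#' the choice-classification percentages to every row.
#'
#' @param plates Data frame with columns `plate_id`, `genotype`,
#'   `assay_type`, `n_toward`, `n_away`, `n_middle`.
#' @param denominator Passed to [choice_index()].
#'
#' @return The input with columns `choice_index`, `pct_correct`,
#'   `pct_wrong`, `pct_no_choice`, `pct_incorrect` appended.
#' @export
score_plates <- function(plates, denominator = "all") {
  stopifnot(is.data.frame(plates))
  needed <- c("assay_type", "n_toward", "n_away", "n_middle")
  missing_cols <- setdiff(needed, names(plates))
  if (length(missing_cols) > 0) {
    stop("plate table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  scored <- lapply(seq_len(nrow(plates)), function(i) {
    row <- plates[i, ]
    cs <- classify_choices(row$n_toward, row$n_away, row$n_middle,
                           row$assay_type)
    cs$choice_index <- choice_index(row$n_toward, row$n_away, row$n_middle,
                                    denominator = denominator)
    cs
  })
  dplyr::bind_cols(tibble::as_tibble(plates), dplyr::bind_rows(scored))
}
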