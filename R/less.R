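#' LESS item score ranges
#'
#' The Landing Error Scoring System rates 17 jump-landing items: items 1-15
#' are binary errors (0/1) and items 16 (sagittal-plane joint displacement:
#' soft/average/stiff) and 17 (overall impression) take values 0/1/2, for a
#' maximal score of 19 (worst landing).
#'
#' @return tibble with columns `item` (1..17) and `max_score`.
#' @export
less_item_ranges <- function() {
  tibble(item = 1:17, max_score = c(rep(1L, 15), 2L, 2L))
}

#' Score one LESS jump
#'
#' Sum of the 17 item scores, after range validation.
#'
#' @param items integer vector of 17 item scores.
#' @return the jump score (0..19).
#' @export
#' @examples
#' score_jump(c(rep(1, 15), 2, 2)) # 19, the worst possible landing
score_jump <- function(items) {
  if (length(items) != 17) abort_swayrisk("expected 17 LESS items")
  items <- as.integer(items)
  rng <- less_item_ranges()$max_score
  bad <- which(is.na(items) | items < 0 | items > rng)
  if (length(bad) > 0) {
    abort_swayrisk(sprintf("LESS item %d out of range (value %s)",
                           bad[1], items[bad[1]]),
                   class = "swayrisk_less_error")
  }
  sum(items)
}

#' Median of the three jump scores
#'
#' @param scores numeric vector of 3 per-jump scores.
#' @return the middle order statistic.
#' @export
median_of_three <- function(scores) {
  if (length(scores) != 3) abort_swayrisk("expected scores from 3 jumps")
  sort(scores)[2]
}

#' Risk label from the median LESS score
#'
#' A median score less than or equal to 5 labels the athlete not at risk
#' (`NR`); a score greater than 5 labels them at risk (`R`).
#'
#' @param median_score numeric median of the three jump scores.
#' @return factor with levels `NR`, `R`.
#' @export
risk_label <- function(median_score) {
  factor(ifelse(median_score <= 5, "NR", "R"), levels = c("NR", "R"))
}

#' Aggregate a LESS item table into per-athlete records
#'
#' @param items_df tibble with columns `athlete_id`, `jump` (1..3) and
#'   `item_1` .. `item_17`.
#' @return tibble with one row per athlete: `athlete_id`, per-jump scores
#'   `score_1..score_3`, `median_score`, `label`.
#' @export
less_records <- function(items_df) {
  item_cols <- paste0("item_", 1:17)
  if (!all(item_cols %in% names(items_df))) {
    abort_swayrisk("items_df must have columns item_1 .. item_17")
  }
  scored <- items_df |>
    dplyr::rowwise() |>
    dplyr::mutate(score = score_jump(dplyr::c_across(all_of(item_cols)))) |>
    dplyr::ungroup()
  scored |>
    dplyr::arrange(.data$athlete_id, .data$jump) |>
    dplyr::group_by(.data$athlete_id) |>
    dplyr::summarise(
      score_1 = .data$score[1], score_2 = .data$score[2],
      score_3 = .data$score[3],
      median_score = median_of_three(.data$score), .groups = "drop"
    ) |>
    dplyr::mutate(label = risk_label(.data$median_score))
}

#' Read / write LESS item tables
#'
#' CSV layout: one row per jump with `athlete_id`, `jump`, `item_1..item_17`.
#'
#' @param path file path.
#' @param items_df the item table.
#' @return the tibble read, or the input invisibly.
#' @export
read_less_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_less_csv
#' @export
write_less_csv <- function(items_df, path) {
  readr::write_csv(items_df, path)
  invisible(items_df)
}
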