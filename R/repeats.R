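# repeat-expansion genotype interpretation for the two expansion loci

REPEAT_LOCI <- c("C9orf72", "ATXN2")

#' Interpret repeat-expansion calls
#'
#' Applies the locus-specific pathogenic thresholds to per-person repeat
#' counts (larger allele): a C9orf72 GGGGCC expansion is pathogenic above 30
#' repeats; an ATXN2 CAG intermediate expansion of 29-33 repeats inclusive is
#' treated as pathogenic (an established ALS risk factor). ATXN2 counts above
#' 33 fall in the full-expansion (SCA2) range: they are flagged in the `note`
#' column but are not ALS-actionable here.
#'
#' @param repeat_calls Data frame with columns `person_id`, `gene`
#'   (`C9orf72` or `ATXN2`) and `repeat_count` (non-negative integer).
#' @return The input as a tibble with logical `pathogenic` and character
#'   `note` (`"sca2_range"` or `NA`) appended.
#' @examples
#' interpret_repeats(data.frame(
#'   person_id = "P1", gene = c("C9orf72", "ATXN2"), repeat_count = c(31, 29)
#' ))
#' @export
interpret_repeats <- function(repeat_calls) {
  check_columns(
    repeat_calls, c("person_id", "gene", "repeat_count"), "repeat calls"
  )
  bad <- setdiff(unique(repeat_calls$gene), REPEAT_LOCI)
  if (length(bad) > 0) {
    stop_input(paste0(
      "Unknown repeat locus: ", paste(bad, collapse = ", "),
      " (expected C9orf72 or ATXN2)."
    ))
  }
  if (any(repeat_calls$repeat_count < 0 |
    repeat_calls$repeat_count != floor(repeat_calls$repeat_count))) {
    stop_input("`repeat_count` must be a non-negative integer.")
  }
  as_tibble(repeat_calls) %>%
    mutate(
      pathogenic = ifelse(.data$gene == "C9orf72",
        .data$repeat_count > 30,
        .data$repeat_count >= 29 & .data$repeat_count <= 33
      ),
      note = ifelse(.data$gene == "ATXN2" & .data$repeat_count > 33,
        "sca2_range", NA_character_
      )
    )
}
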