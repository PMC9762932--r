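# JSON loaders for the shipped configuration artifacts

#' Read a gene panel from a JSON definition
#'
#' Panel JSON files carry `name`, `genes` and `biallelic_only`; the three
#' shipped panels live under `system.file("extdata", package = "alsyield")`
#' as `panel_<name>.json`.
#'
#' @param path Path to a panel JSON file.
#' @return A panel tibble (see [panel_definition()]).
#' @examples
#' read_panel_json(system.file("extdata", "panel_four_gene.json",
#'   package = "alsyield"
#' ))
#' @export
read_panel_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_columns(as.data.frame(spec["name"]), "name", "panel JSON")
  panel_definition(
    spec$name, spec$genes,
    biallelic_only = spec$biallelic_only %||% character()
  )
}

#' Read a fixed-value criteria profile from JSON
#'
#' Profile JSON files carry `name` plus `high` and `moderate` blocks mapping
#' each of the 28 criterion names to `"true"`, `"false"` or `"auto"`. The two
#' shipped profiles live under `system.file("extdata", package = "alsyield")`.
#'
#' @param path Path to a profile JSON file.
#' @return An `als_fixed_profile` (see [fixed_profile()]).
#' @export
read_fixed_profile_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixed_profile(NULL,
    high = unlist(spec$high), moderate = unlist(spec$moderate)
  )
}
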