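# reading and writing the tabular interchange formats

VARIANT_REQUIRED_COLS <- c(
  "person_id", "gene", "chrom", "pos", "ref", "alt", "variant_class",
  "consequence_terms", "site_quality", "genotype_quality", "missingness",
  "af_reference", "af_internal", "zygosity"
)
VARIANT_OPTIONAL_COLS <- c(
  "insilico_score", "clinvar_plp", "alsod_publications", "alsod_patients"
)

validate_variant_table <- function(df) {
  check_columns(df, VARIANT_REQUIRED_COLS, "variant table")
  for (col in c("af_reference", "af_internal", "missingness")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 1)
    if (length(bad) > 0) {
      stop_schema(paste0(
        "Column `", col, "` out of [0, 1] at row(s) ",
        paste(utils::head(bad, 5), collapse = ", "), "."
      ))
    }
  }
  if (any(is.na(df$consequence_terms) | !nzchar(df$consequence_terms))) {
    stop_schema("Column `consequence_terms` must be non-empty for every variant.")
  }
  as_tibble(df)
}

#' Read a per-person annotated variant table
#'
#' Two dialects of the same records are supported. `tsv`: one row per
#' person-variant with the documented columns (see below). `vcf`: a
#' sites-style VCF in which each record is one person-variant, 1-based
#' GRCh37-style coordinates in `CHROM`/`POS`/`REF`/`ALT`, site quality in
#' `QUAL`, and the remaining annotation subfields in INFO keys `PID`
#' (person), `GENE`, `CSQ` (consequence terms, `&`-separated), `VC`
#' (SNV/indel), `GQ`, `MISS`, `AFR`, `AFI` (frequencies in the external and
#' internal reference sets), `ZYG`, and optionally `SCORE`, `CLNPLP`,
#' `ALSOPUB`, `ALSOPAT`. Reading a VCF requires the `vcfR` package.
#'
#' Required fields: person_id, gene, chrom, pos, ref, alt, variant_class,
#' consequence_terms, site_quality, genotype_quality, missingness,
#' af_reference, af_internal, zygosity; optional: insilico_score,
#' clinvar_plp, alsod_publications, alsod_patients. A missing required field
#' or an out-of-range frequency raises a schema error naming the field.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return Validated variant tibble.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input(paste0("File not found: ", path))
  if (dialect == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop_input("Reading the VCF dialect requires the vcfR package.")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info_num <- function(key) {
      suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
    }
    info_chr <- function(key) vcfR::extract.info(v, element = key)
    df <- tibble(
      person_id = info_chr("PID"),
      gene = info_chr("GENE"),
      chrom = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = fix$REF,
      alt = fix$ALT,
      variant_class = info_chr("VC"),
      consequence_terms = info_chr("CSQ"),
      site_quality = suppressWarnings(as.numeric(fix$QUAL)),
      genotype_quality = info_num("GQ"),
      missingness = info_num("MISS"),
      af_reference = info_num("AFR"),
      af_internal = info_num("AFI"),
      zygosity = info_chr("ZYG"),
      insilico_score = info_num("SCORE"),
      clinvar_plp = info_chr("CLNPLP") == "1",
      alsod_publications = as.integer(info_num("ALSOPUB")),
      alsod_patients = as.integer(info_num("ALSOPAT"))
    )
  }
  validate_variant_table(df)
}

#' Write a variant table in either dialect
#'
#' Counterpart of [read_variant_table()]; both dialects round-trip the same
#' records.
#'
#' @param variants Variant tibble.
#' @param path Output path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  variants <- validate_variant_table(variants)
  if (dialect == "tsv") {
    readr::write_tsv(variants, path, progress = FALSE)
    return(invisible(path))
  }
  fmt <- function(x) {
    ifelse(is.na(x), ".", as.character(x))
  }
  info <- paste0(
    "PID=", variants$person_id,
    ";GENE=", variants$gene,
    ";VC=", variants$variant_class,
    ";CSQ=", variants$consequence_terms,
    ";GQ=", variants$genotype_quality,
    ";MISS=", variants$missingness,
    ";AFR=", variants$af_reference,
    ";AFI=", variants$af_internal,
    ";ZYG=", variants$zygosity,
    ";SCORE=", fmt(variants$insilico_score %||% rep(NA, nrow(variants))),
    ";CLNPLP=", fmt(as.integer(variants$clinvar_plp %||% rep(NA, nrow(variants)))),
    ";ALSOPUB=", fmt(variants$alsod_publications %||% rep(NA, nrow(variants))),
    ";ALSOPAT=", fmt(variants$alsod_patients %||% rep(NA, nrow(variants)))
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh37",
    paste0(
      "##INFO=<ID=", c(
        "PID,Number=1,Type=String,Description=\"Person id\"",
        "GENE,Number=1,Type=String,Description=\"Gene symbol\"",
        "VC,Number=1,Type=String,Description=\"Variant class (SNV/indel)\"",
        "CSQ,Number=1,Type=String,Description=\"Consequence terms\"",
        "GQ,Number=1,Type=Float,Description=\"Genotype quality\"",
        "MISS,Number=1,Type=Float,Description=\"Missingness\"",
        "AFR,Number=1,Type=Float,Description=\"External reference AF\"",
        "AFI,Number=1,Type=Float,Description=\"Internal control AF\"",
        "ZYG,Number=1,Type=String,Description=\"Zygosity\"",
        "SCORE,Number=1,Type=Float,Description=\"In-silico score\"",
        "CLNPLP,Number=1,Type=Integer,Description=\"ClinVar P/LP flag\"",
        "ALSOPUB,Number=1,Type=Integer,Description=\"ALSoD publications\"",
        "ALSOPAT,Number=1,Type=Integer,Description=\"ALSoD patients\""
      ), ">"
    ),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- paste(
    variants$chrom, variants$pos, ".", variants$ref, variants$alt,
    variants$site_quality, "PASS", info,
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the same formats the pipeline reads: `variants.tsv`,
#' `sample_metrics.tsv`, `repeat_calls.tsv`, `persons.tsv` and the
#' ground-truth sidecar `truth.json`.
#'
#' @param cohort An `als_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cohort$variants, file.path(dir, "variants.tsv"),
    progress = FALSE
  )
  readr::write_tsv(cohort$sample_metrics,
    file.path(dir, "sample_metrics.tsv"),
    progress = FALSE
  )
  readr::write_tsv(cohort$repeat_calls, file.path(dir, "repeat_calls.tsv"),
    progress = FALSE
  )
  readr::write_tsv(cohort$persons, file.path(dir, "persons.tsv"),
    progress = FALSE
  )
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
    dataframe = "rows", na = "null", digits = NA
  )
  invisible(dir)
}
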