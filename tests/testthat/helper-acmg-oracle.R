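# Independent brute-force transcription of the published ACMG combining
# table, deliberately written scalar-wise and rule-by-rule (not shared with
# the package implementation) so the two can be compared by enumeration.

oracle_acmg_class <- function(flags) {
  stopifnot(length(flags) == 28)
  pvs1 <- flags[["PVS1"]]
  ps <- sum(flags[paste0("PS", 1:4)])
  pm <- sum(flags[paste0("PM", 1:6)])
  pp <- sum(flags[paste0("PP", 1:5)])
  ba1 <- flags[["BA1"]]
  bs <- sum(flags[paste0("BS", 1:4)])
  bp <- sum(flags[paste0("BP", 1:7)])

  pathogenic_rules <- c(
    pvs1 && ps >= 1,
    pvs1 && pm >= 2,
    pvs1 && pm == 1 && pp == 1,
    pvs1 && pp >= 2,
    ps >= 2,
    ps == 1 && pm >= 3,
    ps == 1 && pm == 2 && pp >= 2,
    ps == 1 && pm == 1 && pp >= 4
  )
  likely_pathogenic_rules <- c(
    pvs1 && pm == 1,
    ps == 1 && pm >= 1 && pm <= 2,
    ps == 1 && pp >= 2,
    pm >= 3,
    pm == 2 && pp >= 2,
    pm == 1 && pp >= 4
  )
  benign_rules <- c(ba1, bs >= 2)
  likely_benign_rules <- c(bs == 1 && bp == 1, bp >= 2)

  p_side <- any(pathogenic_rules) || any(likely_pathogenic_rules)
  b_side <- any(benign_rules) || any(likely_benign_rules)
  if (p_side && b_side) {
    return("vus")
  }
  if (any(pathogenic_rules)) {
    return("pathogenic")
  }
  if (any(likely_pathogenic_rules)) {
    return("likely_pathogenic")
  }
  if (any(benign_rules)) {
    return("benign")
  }
  if (any(likely_benign_rules)) {
    return("likely_benign")
  }
  "vus"
}

# evidence tibble from a list of active-criterion character vectors
evidence_from_sets <- function(sets) {
  m <- matrix(FALSE, length(sets), 28,
    dimnames = list(NULL, alsyield::acmg_criteria())
  )
  for (i in seq_along(sets)) m[i, sets[[i]]] <- TRUE
  tibble::as_tibble(as.data.frame(m))
}

# all evidence profiles with at most `k` active flags, as a logical matrix
enumerate_profiles <- function(k) {
  crits <- alsyield::acmg_criteria()
  rows <- list(matrix(FALSE, 1, 28, dimnames = list(NULL, crits)))
  for (size in seq_len(k)) {
    combos <- utils::combn(28, size)
    m <- matrix(FALSE, ncol(combos), 28, dimnames = list(NULL, crits))
    for (j in seq_len(ncol(combos))) m[j, combos[, j]] <- TRUE
    rows[[size + 1]] <- m
  }
  do.call(rbind, rows)
}

oracle_classes <- function(mat) {
  apply(mat, 1, function(r) oracle_acmg_class(as.logical(r) |>
    stats::setNames(colnames(mat))))
}
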