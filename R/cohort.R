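#' Classify twin pairs by phenotype concordance
#'
#' Each complete pair (exactly two members) is labeled `discordant` (one
#' affected), `concordant_affected` (both affected) or `concordant_healthy`
#' (both healthy). Pairs with a number of members other than two, or with
#' inconsistent zygosity between members, are dropped with a message.
#'
#' @param metadata data.frame with `sample_id`, `pair_id`, `zygosity`
#'   ("MZ"/"DZ") and `md` (0/1).
#' @return data.frame of class `pair_classification` with one row per pair
#'   (`pair_id`, `zygosity`, `class`) and a `"summary"` attribute: the
#'   zygosity x class count table.
#' @export
classify_pairs <- function(metadata) {
  stopifnot(all(c("pair_id", "zygosity", "md") %in% names(metadata)))
  sizes <- table(metadata$pair_id)
  bad <- names(sizes)[sizes != 2L]
  if (length(bad)) {
    message("dropping ", length(bad), " pair(s) without exactly 2 members")
    metadata <- metadata[!metadata$pair_id %in% bad, , drop = FALSE]
  }
  if (nrow(metadata) == 0L) stop("no complete pairs in metadata")
  sp <- split(metadata, metadata$pair_id)
  zyg <- vapply(sp, function(d) {
    if (length(unique(d$zygosity)) != 1L) NA_character_ else d$zygosity[1L]
  }, character(1L))
  if (anyNA(zyg)) {
    message("dropping ", sum(is.na(zyg)), " pair(s) with inconsistent zygosity")
    sp <- sp[!is.na(zyg)]
    zyg <- zyg[!is.na(zyg)]
  }
  n_md <- vapply(sp, function(d) sum(d$md), numeric(1L))
  cls <- c("concordant_healthy", "discordant", "concordant_affected")[n_md + 1L]
  out <- data.frame(pair_id = names(sp), zygosity = zyg, class = cls,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "summary") <- table(zygosity = out$zygosity,
                                class = factor(out$class,
                                               levels = c("discordant",
                                                          "concordant_affected",
                                                          "concordant_healthy")))
  class(out) <- c("pair_classification", "data.frame")
  out
}

#' Phenotype prevalence among individuals
#'
#' Affected individuals divided by all individuals, optionally restricted to
#' one zygosity group.
#'
#' @param metadata data.frame with `zygosity` and `md`.
#' @param zygosity `NULL` (all individuals), "MZ" or "DZ".
#' @return Proportion in \[0, 1\].
#' @export
prevalence <- function(metadata, zygosity = NULL) {
  if (!is.null(zygosity))
    metadata <- metadata[metadata$zygosity == zygosity, , drop = FALSE]
  if (nrow(metadata) == 0L) stop("no individuals in the requested group")
  mean(metadata$md == 1)
}

#' Proband-wise concordance
#'
#' The probability that the co-twin of an affected individual is also
#' affected, computed from pair counts with the standard twin-study formula
#' `2C / (2C + D)` where `C` is the number of concordant-affected pairs and
#' `D` the number of discordant pairs.
#'
#' @param n_concordant_affected Number of pairs with both members affected.
#' @param n_discordant Number of pairs with exactly one member affected.
#' @return Proportion in \[0, 1\].
#' @export
proband_concordance <- function(n_concordant_affected, n_discordant) {
  C <- n_concordant_affected; D <- n_discordant
  stopifnot(C >= 0, D >= 0)
  if (2 * C + D == 0)
    stop("proband-wise concordance undefined: no affected individuals")
  2 * C / (2 * C + D)
}

#' Zygosity association tests on the cohort contingency tables
#'
#' Assembles the four cohort contingency comparisons and tests each for
#' independence. Where a comparison can be counted either per pair or per
#' individual, both constructions are emitted, labeled with a
#' `_pairs`/`_individuals` suffix:
#' \describe{
#'   \item{zygosity_vs_md}{individuals: zygosity x disease status}
#'   \item{zygosity_vs_concordance}{zygosity x (member of a concordant vs
#'     discordant pair), per pair and per individual}
#'   \item{concordance_among_affected}{affected individuals: zygosity x
#'     whether their pair is concordant}
#'   \item{md_among_concordant}{concordant pairs/individuals: zygosity x
#'     (affected vs healthy)}
#' }
#' Pearson chi-square is used, reported both with Yates continuity
#' correction (the default for 2x2 tables) and without; when any expected
#' cell is below 1 a Fisher exact test is substituted with a warning. A
#' table with an all-zero row or column is an error.
#'
#' @param metadata Individual-level metadata (see [classify_pairs()]).
#' @param correct Use Yates continuity correction for the headline p-value
#'   (default `TRUE`).
#' @return data.frame with one row per comparison: `comparison`,
#'   `statistic`, `p`, `p_uncorrected`, `test`, and a readable `table`
#'   description. The underlying 2x2 tables are in the `"tables"` attribute.
#' @export
zygosity_association_tests <- function(metadata, correct = TRUE) {
  pc <- classify_pairs(metadata)
  metadata <- metadata[metadata$pair_id %in% pc$pair_id, , drop = FALSE]
  pair_class <- pc$class[match(metadata$pair_id, pc$pair_id)]
  tabs <- list(
    zygosity_vs_md = table(zygosity = metadata$zygosity,
                           md = metadata$md),
    zygosity_vs_concordance_pairs =
      table(zygosity = pc$zygosity, concordant = pc$class != "discordant"),
    zygosity_vs_concordance_individuals =
      table(zygosity = metadata$zygosity,
            concordant = pair_class != "discordant"),
    concordance_among_affected = {
      aff <- metadata$md == 1
      table(zygosity = metadata$zygosity[aff],
            concordant = pair_class[aff] == "concordant_affected")
    },
    md_among_concordant_pairs = {
      conc <- pc[pc$class != "discordant", , drop = FALSE]
      table(zygosity = conc$zygosity,
            both_md = conc$class == "concordant_affected")
    },
    md_among_concordant_individuals = {
      conc <- pair_class != "discordant"
      table(zygosity = metadata$zygosity[conc], md = metadata$md[conc])
    }
  )
  rows <- lapply(names(tabs), function(nm) {
    tb <- tabs[[nm]]
    if (any(dim(tb) < 2L) || any(rowSums(tb) == 0) || any(colSums(tb) == 0))
      stop("degenerate contingency table for '", nm, "'")
    expected <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    if (any(expected < 1)) {
      warning("expected cell < 1 in '", nm, "'; using Fisher exact test")
      ft <- stats::fisher.test(tb)
      data.frame(comparison = nm, statistic = NA_real_, p = ft$p.value,
                 p_uncorrected = ft$p.value, test = "fisher",
                 table = format_table_2x2(tb), stringsAsFactors = FALSE)
    } else {
      chi_c <- suppressWarnings(stats::chisq.test(tb, correct = TRUE))
      chi_u <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
      main <- if (correct) chi_c else chi_u
      data.frame(comparison = nm,
                 statistic = unname(main$statistic),
                 p = main$p.value,
                 p_uncorrected = chi_u$p.value,
                 test = if (correct) "chisq_yates" else "chisq",
                 table = format_table_2x2(tb), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "tables") <- tabs
  out
}

format_table_2x2 <- function(tb) {
  paste(apply(tb, 1L, paste, collapse = "/"), collapse = " | ")
}

#' Cohort summary in the style of a twin-study "Table 1"
#'
#' @param metadata Individual-level metadata.
#' @return data.frame of labeled counts and proportions: pair classes per
#'   zygosity, totals, prevalence and proband-wise concordance per
#'   zygosity.
#' @export
cohort_summary <- function(metadata) {
  pc <- classify_pairs(metadata)
  s <- attr(pc, "summary")
  zygs <- rownames(s)
  rows <- list()
  for (z in c("MZ", "DZ")) {
    if (!z %in% zygs) next
    C <- s[z, "concordant_affected"]; D <- s[z, "discordant"]
    rows[[z]] <- data.frame(
      zygosity = z,
      discordant_pairs = D,
      concordant_affected_pairs = C,
      concordant_healthy_pairs = s[z, "concordant_healthy"],
      total_pairs = sum(s[z, ]),
      prevalence = prevalence(metadata, z),
      proband_concordance = if (2 * C + D > 0)
        proband_concordance(C, D) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "total_pairs") <- nrow(pc)
  out
}
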