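#' Red-blood-cell contaminant accessions
#'
#' UniProt accessions of proteins highly abundant in (nucleated, avian) red
#' blood cells, excluded by default from label-free quantification to
#' correct for blood contamination of muscle samples.
#'
#' @return character vector of accessions.
#' @export
rbc_accessions <- function() {
  c("A0A674HE74", "B5FXM1", "B5G3P7", "H0ZSY4", "A0A674HG19")
}

#' Histone H4 UniProt accession (normalization anchor)
#' @return a single accession string.
#' @export
h4_accession <- function() "B5FXC8"

#' Top-3 label-free quantification and normalization of one sample
#'
#' Turns a peptide LC-peak table into per-protein abundances: (1) rows whose
#' accession is on the exclusion list (default: the five red-blood-cell
#' contaminants) are dropped by exact accession match; (2) peptides flagged
#' as shared across the fast-MyHC cluster (`myh_fast_cluster` column) are
#' pooled into a single `MYH-fast` pseudo-protein (MYH13 stays separate);
#' (3) duplicate (protein, peptide) rows keep their largest area; (4) each
#' protein is quantified as the sum of its 3 largest peptide areas (all
#' areas when fewer than 3 peptides); (5) abundances are normalized both to
#' the total sum of peaks (`rel_total`) and to Histone H4 (`rel_h4`);
#' (6) a functional category is attached from `category_map` (default
#' `"other"`).
#'
#' @param table data.frame with columns `accession`, `peptide`, `area`, and
#'   optionally `gene`, `sample`, `myh_fast_cluster` (logical).
#' @param category_map optional data.frame with columns `accession`,
#'   `category` (levels: sarcomeric, ca_handling, mitochondrial, other).
#' @param exclude accessions to drop, default [rbc_accessions()].
#' @param h4 accession of Histone H4, default [h4_accession()].
#' @param include_h4_in_total whether H4 itself enters the total-sum
#'   denominator, default TRUE.
#' @param sample restrict the table to this `sample` id; required when the
#'   table holds several samples.
#' @return data.frame of class `protein_profiles`: `protein`, `gene`,
#'   `category`, `raw_top3`, `rel_total`, `rel_h4`,
#'   `is_myh_fast_aggregate`.
#' @export
quantify_and_normalize <- function(table, category_map = NULL,
                                   exclude = rbc_accessions(),
                                   h4 = h4_accession(),
                                   include_h4_in_total = TRUE,
                                   sample = NULL) {
  stopifnot(all(c("accession", "peptide", "area") %in% names(table)))
  if (nrow(table) == 0L) stop("empty peptide table")
  if (!is.null(sample) && "sample" %in% names(table))
    table <- table[table$sample == sample, , drop = FALSE]
  if ("sample" %in% names(table) && length(unique(table$sample)) > 1L)
    stop("table holds several samples; pass 'sample'")
  if (nrow(table) == 0L) stop("empty peptide table")
  if (any(table$area < 0)) stop("peak areas must be non-negative")
  table <- table[!(table$accession %in% exclude), , drop = FALSE]
  if (nrow(table) == 0L) stop("all rows excluded")
  if ("myh_fast_cluster" %in% names(table)) {
    pool <- isTRUE_vec(table$myh_fast_cluster)
    table$accession[pool] <- "MYH-fast"
    if ("gene" %in% names(table)) table$gene[pool] <- "MYH-fast"
  }
  # de-duplicate (protein, peptide): keep the largest area (redundant peaks)
  key <- paste(table$accession, table$peptide, sep = "\r")
  ord <- order(key, -table$area)
  table <- table[ord, , drop = FALSE]
  table <- table[!duplicated(key[ord]), , drop = FALSE]

  top3 <- function(a) sum(sort(a, decreasing = TRUE)[seq_len(min(3L, length(a)))])
  raw <- tapply(table$area, table$accession, top3)
  prot <- names(raw); raw <- as.numeric(raw)
  gene <- if ("gene" %in% names(table))
    table$gene[match(prot, table$accession)] else prot
  total <- if (include_h4_in_total) sum(raw) else sum(raw[prot != h4])
  rel_total <- raw / total
  if (h4 %in% prot) {
    rel_h4 <- raw / raw[prot == h4]
  } else {
    warning("Histone H4 absent; rel_h4 omitted")
    rel_h4 <- rep(NA_real_, length(raw))
  }
  category <- rep("other", length(prot))
  if (!is.null(category_map)) {
    i <- match(prot, category_map$accession)
    category[!is.na(i)] <- as.character(category_map$category[i[!is.na(i)]])
  }
  out <- data.frame(protein = prot, gene = gene, category = category,
                    raw_top3 = raw, rel_total = rel_total, rel_h4 = rel_h4,
                    is_myh_fast_aggregate = prot == "MYH-fast")
  rownames(out) <- NULL
  class(out) <- c("protein_profiles", "data.frame")
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Paired differential protein abundance
#'
#' Compares per-protein abundances between paired intact and treated samples
#' (same animals). The fold change is the geometric mean of per-pair
#' treated/intact ratios (equivalently `2^mean(log2 ratios)`), tested with a
#' paired two-sided t-test on the per-pair log2 differences; an unpaired
#' two-sided Welch's t-test on log2 abundances is available as
#' `method = "welch"`. Raw p-values are reported (Benjamini-Hochberg
#' adjustment behind `bh = TRUE`). Category rollups sum `rel_total` per
#' functional category and condition; the volcano table carries log2 fold
#' change against -log10 p.
#'
#' @param intact,treated lists of `protein_profiles` (one per sample), in
#'   pairing order.
#' @param measure abundance measure: `"rel_h4"` (default), `"rel_total"` or
#'   `"raw_top3"`.
#' @param method `"paired"` (default) or `"welch"`.
#' @param bh apply Benjamini-Hochberg correction, default FALSE.
#' @return list of class `differential_abundance`: `proteins` (data.frame
#'   `protein, category, n_pairs, mean_ratio, log2fc, p` and `p_adj` if
#'   requested; proteins missing from a condition keep `NA` fold change and
#'   are excluded from tests), `categories` (summed `rel_total` per category
#'   per condition), `volcano` (`protein, log2fc, neg_log10_p`).
#' @export
differential_abundance <- function(intact, treated,
                                   measure = c("rel_h4", "rel_total",
                                               "raw_top3"),
                                   method = c("paired", "welch"),
                                   bh = FALSE) {
  measure <- match.arg(measure); method <- match.arg(method)
  stopifnot(length(intact) == length(treated), length(intact) >= 2L)
  n <- length(intact)
  get <- function(prof, p) {
    i <- match(p, prof$protein)
    prof[[measure]][i]
  }
  prots <- sort(unique(unlist(c(lapply(intact, `[[`, "protein"),
                                lapply(treated, `[[`, "protein")))))
  cat_of <- rep("other", length(prots))
  for (prof in c(intact, treated)) {
    i <- match(prof$protein, prots)
    cat_of[i] <- prof$category
  }
  rows <- lapply(seq_along(prots), function(k) {
    p <- prots[k]
    a <- vapply(intact, get, 0, p = p)
    b <- vapply(treated, get, 0, p = p)
    ok <- is.finite(a) & is.finite(b) & a > 0 & b > 0
    if (sum(ok) < 2L)
      return(data.frame(protein = p, category = cat_of[k], n_pairs = sum(ok),
                        mean_ratio = NA_real_, log2fc = NA_real_,
                        p = NA_real_))
    l2 <- log2(b[ok]) - log2(a[ok])
    pv <- if (method == "paired") {
      if (stats::sd(l2) == 0) as.numeric(all(l2 == 0)) * 1 else
        stats::t.test(l2)$p.value
    } else {
      # degenerate (constant) data: p = 1 when means agree, else 0
      tryCatch(stats::t.test(log2(b[ok]), log2(a[ok]))$p.value,
               error = function(e)
                 as.numeric(isTRUE(all.equal(mean(log2(b[ok])),
                                             mean(log2(a[ok]))))))
    }
    data.frame(protein = p, category = cat_of[k], n_pairs = sum(ok),
               mean_ratio = 2^mean(l2), log2fc = mean(l2), p = pv)
  })
  proteins <- do.call(rbind, rows)
  if (bh) proteins$p_adj <- stats::p.adjust(proteins$p, "BH")
  roll <- function(profs, cond) {
    per <- lapply(profs, function(pr)
      tapply(pr$rel_total, pr$category, sum))
    cats <- sort(unique(unlist(lapply(per, names))))
    m <- sapply(per, function(v) { x <- v[cats]; x[is.na(x)] <- 0; x })
    if (is.null(dim(m))) m <- matrix(m, nrow = length(cats))
    data.frame(category = cats, condition = cond,
               rel_abundance = rowMeans(m))
  }
  categories <- rbind(roll(intact, "intact"), roll(treated, "treated"))
  volcano <- data.frame(protein = proteins$protein,
                        log2fc = proteins$log2fc,
                        neg_log10_p = -log10(proteins$p))
  structure(list(proteins = proteins, categories = categories,
                 volcano = volcano, measure = measure, method = method),
            class = "differential_abundance")
}

#' @export
print.differential_abundance <- function(x, ...) {
  tested <- sum(!is.na(x$proteins$p))
  sig <- sum(x$proteins$p < 0.05, na.rm = TRUE)
  dec <- sum(x$proteins$p < 0.05 & x$proteins$log2fc < 0, na.rm = TRUE)
  cat(sprintf(paste0("<differential_abundance (%s, %s): %d proteins, ",
                     "%d tested, %d significant (%d decreasing)>\n"),
              x$measure, x$method, nrow(x$proteins), tested, sig, dec))
  invisible(x)
}
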