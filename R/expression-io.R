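#' Gene annotation for normalization
#'
#' Bundles the protein-coding gene set and (optionally) effective gene
#' lengths. Lengths are required only for [countsToTpm()].
#'
#' @param proteinCoding character vector of protein-coding gene ids.
#' @param geneLengths named numeric vector of effective lengths in base pairs
#'   (strictly positive), or `NULL`.
#' @return An object of class `"GeneAnnotation"` (a validated list).
#' @examples
#' ann <- geneAnnotation(c("g1", "g2"), c(g1 = 1000, g2 = 1500))
#' @export
geneAnnotation <- function(proteinCoding, geneLengths = NULL) {
  proteinCoding <- unique(as.character(proteinCoding))
  if (!is.null(geneLengths)) {
    if (is.null(names(geneLengths)) || any(!nzchar(names(geneLengths)))) {
      stop("geneLengths must be named by gene id")
    }
    if (any(!is.finite(geneLengths)) || any(geneLengths <= 0)) {
      stop("gene lengths must be strictly positive")
    }
  }
  structure(list(proteinCoding = proteinCoding, geneLengths = geneLengths),
            class = "GeneAnnotation")
}

#' Read a delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of gene ids; all
#' remaining cells numeric. The field separator is inferred from the file
#' extension (`.csv` is comma, anything else tab) unless given explicitly.
#' Orientation is fixed: genes in rows, samples in columns.
#'
#' @param path file path.
#' @param scale the scale tag of the stored values (see
#'   [ExpressionMatrix-class]).
#' @param sep field separator; `NULL` (default) infers from the extension.
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path, scale = c("rpkm", "counts", "tpm", "log2tpm"),
                                 sep = NULL) {
  scale <- match.arg(scale)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  flds <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(flds)) > 1L) {
    stop(sprintf("ragged rows in '%s': lines carry %s fields", path,
                 paste(unique(flds), collapse = "/")))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", fill = FALSE)
  if (nrow(df) == 0L) stop(sprintf("no genes in '%s' (header only)", path))
  if (ncol(df) < 2L) stop(sprintf("no sample columns in '%s'", path))
  genes <- df[[1L]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop(sprintf("duplicated gene id(s) in '%s': %s", path,
                 paste(dup, collapse = ", ")))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at data row %d, column '%s' of '%s'",
                 vals[bad[1, 1], bad[1, 2]], bad[1, 1],
                 colnames(vals)[bad[1, 2]], path))
  }
  dimnames(num) <- list(genes, colnames(vals))
  ExpressionMatrix(num, scale)
}

#' Write an expression matrix as delimited text
#'
#' @param m an [ExpressionMatrix-class].
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(m, path) {
  stopifnot(is(m, "ExpressionMatrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  v <- exprValues(m)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert RPKM to TPM
#'
#' Per sample j, `TPM[i, j] = RPKM[i, j] / sum_i(RPKM[i, j]) * 1e6`, so every
#' column sums to one million.
#'
#' @param m an [ExpressionMatrix-class] on the `rpkm` scale.
#' @return An [ExpressionMatrix-class] on the `tpm` scale.
#' @export
rpkmToTpm <- function(m) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (exprScale(m) != "rpkm") stop("rpkmToTpm requires scale 'rpkm'")
  v <- exprValues(m)
  cs <- colSums(v)
  if (any(cs <= 0)) {
    stop(sprintf("all-zero expression column(s): %s",
                 paste(colnames(v)[cs <= 0], collapse = ", ")))
  }
  ExpressionMatrix(sweep(v, 2L, cs, "/") * TPM_TOTAL, "tpm")
}

#' Convert raw counts to TPM
#'
#' Counts are first divided by effective gene length (reads per base), then
#' each sample is rescaled to sum to one million:
#' `rate = counts / length; TPM = rate / sum(rate) * 1e6`.
#'
#' @param m an [ExpressionMatrix-class] on the `counts` scale.
#' @param ann a [geneAnnotation()] carrying lengths for every gene in `m`.
#' @return An [ExpressionMatrix-class] on the `tpm` scale.
#' @export
countsToTpm <- function(m, ann) {
  stopifnot(is(m, "ExpressionMatrix"), inherits(ann, "GeneAnnotation"))
  if (exprScale(m) != "counts") stop("countsToTpm requires scale 'counts'")
  if (is.null(ann$geneLengths)) stop("gene lengths are required for counts -> TPM")
  miss <- setdiff(geneIds(m), names(ann$geneLengths))
  if (length(miss)) {
    stop(sprintf("missing gene length(s) for: %s", paste(miss, collapse = ", ")))
  }
  v <- exprValues(m)
  rate <- v / ann$geneLengths[rownames(v)]
  cs <- colSums(rate)
  if (any(cs <= 0)) {
    stop(sprintf("all-zero expression column(s): %s",
                 paste(colnames(v)[cs <= 0], collapse = ", ")))
  }
  ExpressionMatrix(sweep(rate, 2L, cs, "/") * TPM_TOTAL, "tpm")
}

#' Log2-transform a TPM matrix
#'
#' Applies `log2(x + pseudocount)` entrywise. The default pseudocount of 1
#' keeps zero TPM at exactly zero and the map strictly increasing, so
#' within-sample gene ordering is preserved.
#'
#' @param m an [ExpressionMatrix-class] on the `tpm` scale.
#' @param pseudocount positive offset added before taking log2.
#' @return An [ExpressionMatrix-class] on the `log2tpm` scale.
#' @export
log2Normalize <- function(m, pseudocount = 1) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (exprScale(m) != "tpm") stop("log2Normalize requires scale 'tpm'")
  stopifnot_scalar_number(pseudocount, "pseudocount")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  ExpressionMatrix(log2(exprValues(m) + pseudocount), "log2tpm")
}

#' Keep only protein-coding genes
#'
#' Retains exactly the genes listed as protein-coding in the annotation,
#' preserving the original row order.
#'
#' @param m an [ExpressionMatrix-class] (any scale).
#' @param ann a [geneAnnotation()].
#' @return An [ExpressionMatrix-class] restricted to protein-coding genes.
#' @export
filterProteinCoding <- function(m, ann) {
  stopifnot(is(m, "ExpressionMatrix"), inherits(ann, "GeneAnnotation"))
  keep <- geneIds(m) %in% ann$proteinCoding
  if (!any(keep)) stop("no protein-coding genes retained; check the annotation")
  ExpressionMatrix(exprValues(m)[keep, , drop = FALSE], exprScale(m))
}

RULES_COLS <- c("drug", "rank", "gene_a", "gene_b", "direction")

validateRulesTable <- function(df) {
  if (!all(RULES_COLS %in% names(df))) {
    stop(sprintf("rules table must have columns: %s",
                 paste(RULES_COLS, collapse = ", ")))
  }
  if (any(df$direction != "a_gt_b_votes_sensitive")) {
    stop("direction must be 'a_gt_b_votes_sensitive'")
  }
  for (d in unique(df$drug)) {
    sub <- df[df$drug == d, , drop = FALSE]
    if (!identical(sort(as.integer(sub$rank)), seq_len(nrow(sub)))) {
      stop(sprintf("drug '%s': ranks must be 1..k with no gaps", d))
    }
    genes <- c(sub$gene_a, sub$gene_b)
    if (anyDuplicated(genes)) {
      stop(sprintf("drug '%s': genes must be disjoint across rules", d))
    }
  }
  df[order(df$drug, df$rank), , drop = FALSE]
}

#' Write fitted kTSP models as a rules table (CSV)
#'
#' One row per rule with columns `drug,rank,gene_a,gene_b,direction`;
#' direction is always `a_gt_b_votes_sensitive` (observing
#' `gene_a > gene_b` votes for sensitivity). Round-trips losslessly with
#' [readRulesTable()].
#'
#' @param models named list of [KTSPModel-class] objects (names = drug ids).
#' @param path output CSV path.
#' @return The written data.frame, invisibly.
#' @export
writeRulesTable <- function(models, path) {
  if (!length(models) || is.null(names(models))) {
    stop("models must be a non-empty named list (names = drug ids)")
  }
  rows <- lapply(names(models), function(d) {
    r <- modelRules(models[[d]])
    data.frame(drug = d, rank = seq_len(nrow(r)), gene_a = r$geneA,
               gene_b = r$geneB, direction = "a_gt_b_votes_sensitive",
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- validateRulesTable(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read and validate a rules table (CSV)
#'
#' @param path CSV path with header `drug,rank,gene_a,gene_b,direction`.
#' @return data.frame, validated (contiguous ranks, gene-disjoint per drug),
#'   ordered by drug then rank.
#' @export
readRulesTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$rank <- as.integer(df$rank)
  validateRulesTable(df)
}
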