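#' Per-population mean expression
#'
#' @param expr gene x sample log2 expression matrix.
#' @param samples sample sheet with `sample`, `population`.
#' @return gene x population matrix of replicate means (columns SPR, DP,
#'   SPF where present).
#' @export
population_means <- function(expr, samples) {
  stopifnot(all(colnames(expr) == samples$sample))
  pops <- unique(samples$population)
  out <- vapply(pops, function(p) {
    rowMeans(expr[, samples$population == p, drop = FALSE])
  }, numeric(nrow(expr)))
  colnames(out) <- pops
  out
}

#' Differentially expressed genes between population pairs
#'
#' For each of the three population pairs, flags genes whose replicate
#' means differ by at least `log2(fc_threshold)` with a Welch t-test
#' p-value below `p_threshold` (raw p-values; the selection rule is a
#' fold-change + raw-p cut, not an FDR procedure). Genes constant across
#' all replicates of a pair are excluded from that pair with a warning.
#'
#' @param expr gene x sample log2 matrix.
#' @param samples sample sheet (`sample`, `population`).
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param p_threshold raw p-value threshold (default 0.05).
#' @return list with `flags` (gene x pair logical matrix, pairs
#'   `SPR_DP`, `SPR_SPF`, `DP_SPF`), `union` (character vector of genes
#'   flagged in any pair) and `n_per_pair`.
#' @export
differential_genes <- function(expr, samples, fc_threshold = 2,
                               p_threshold = 0.05) {
  if (min(table(samples$population)) < 2) {
    stopf("need >= 2 replicates per population")
  }
  pairs <- list(SPR_DP = c("SPR", "DP"), SPR_SPF = c("SPR", "SPF"),
                DP_SPF = c("DP", "SPF"))
  lfc <- log2(fc_threshold)
  flags <- sapply(pairs, function(p) {
    a <- expr[, samples$population == p[1], drop = FALSE]
    b <- expr[, samples$population == p[2], drop = FALSE]
    diff_ok <- abs(rowMeans(a) - rowMeans(b)) >= lfc
    constant <- apply(cbind(a, b), 1, function(x) stats::sd(x) == 0)
    if (any(constant)) {
      warnf("%d gene(s) constant across replicates excluded from pair %s",
            sum(constant), paste(p, collapse = "-"))
    }
    pv <- rep(NA_real_, nrow(expr))
    test_idx <- which(!constant)
    pv[test_idx] <- vapply(test_idx, function(i) {
      x <- a[i, ]; y <- b[i, ]
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        # noise-free groups: distinct means separate perfectly
        return(if (mean(x) == mean(y)) NA_real_ else 0)
      }
      stats::t.test(x, y, var.equal = FALSE)$p.value
    }, numeric(1))
    !is.na(pv) & pv < p_threshold & diff_ok
  })
  rownames(flags) <- rownames(expr)
  list(flags = flags,
       union = rownames(expr)[rowSums(flags) > 0],
       n_per_pair = colSums(flags))
}

#' Similarity index of DP expression on the SPR--SPF axis
#'
#' Linear placement of the DP mean between the two single-positive means in
#' log2 space: `s = 2 * (mean_DP - mean_SPF) / (mean_SPR - mean_SPF) - 1`,
#' so `s = 1` when DP matches SPR and `s = -1` when DP matches SPF.
#' Undefined (NA) when the SPR--SPF separation falls below
#' `denominator_floor`, where the index would blow up.
#'
#' @param mean_spr,mean_dp,mean_spf per-gene population means (log2),
#'   vectorised.
#' @param denominator_floor minimum `|mean_SPR - mean_SPF|` in log2 units
#'   (default 0.25).
#' @return numeric vector of similarity indices (NA where undefined).
#' @export
similarity_index <- function(mean_spr, mean_dp, mean_spf,
                             denominator_floor = 0.25) {
  den <- mean_spr - mean_spf
  s <- 2 * (mean_dp - mean_spf) / den - 1
  s[abs(den) < denominator_floor] <- NA_real_
  s
}

#' Bin similarity indices into the four-way classification
#'
#' Breakpoints at -1.5, -0.5, 0.5 and 1.5: `[-1.5, -0.5)` SPF-like,
#' `[-0.5, 0.5)` intermediate, `[0.5, 1.5]` SPR-like; indices below -1.5
#' or above 1.5 mark genes whose DP expression is distinct from both
#' single-positive populations.
#'
#' @param s numeric vector of similarity indices (NA allowed).
#' @return list with `bin` (factor: SPF-like, intermediate, SPR-like,
#'   distinct-low, distinct-high, undefined) and `fractions` (proportions
#'   over defined indices).
#' @export
bin_similarity <- function(s) {
  levels <- c("SPF-like", "intermediate", "SPR-like",
              "distinct-low", "distinct-high", "undefined")
  bin <- ifelse(is.na(s), "undefined",
         ifelse(s < -1.5, "distinct-low",
         ifelse(s < -0.5, "SPF-like",
         ifelse(s < 0.5, "intermediate",
         ifelse(s <= 1.5, "SPR-like", "distinct-high")))))
  bin <- factor(bin, levels = levels)
  defined <- factor(bin[bin != "undefined"], levels = levels[1:5])
  fractions <- if (length(defined)) {
    prop.table(table(defined))
  } else {
    table(defined)
  }
  list(bin = bin, fractions = fractions)
}

#' Pearson correlation of population mean expression
#'
#' Correlation matrix of the per-gene population means; summarises which
#' populations share expression programs (diagonal 1 by construction).
#'
#' @inheritParams population_means
#' @param min_genes minimum number of genes (default 50).
#' @return population x population correlation matrix.
#' @export
population_correlation <- function(expr, samples, min_genes = 50) {
  if (nrow(expr) < min_genes) stopf("need >= %d genes", min_genes)
  stats::cor(population_means(expr, samples))
}

#' Full similarity-index analysis of an expression table
#'
#' Convenience wrapper: selects the DE union, computes per-gene similarity
#' indices and bins, and summarises bin fractions over the DE set.
#'
#' @param table an `expression_table` (list with `expr`, `samples`) or a
#'   list with those fields.
#' @param fc_threshold,p_threshold see [differential_genes()].
#' @param denominator_floor see [similarity_index()].
#' @return list with `per_gene` (data frame: gene_id, de, similarity, bin),
#'   `de` (the [differential_genes()] result), `fractions` (bin proportions
#'   over DE genes with defined indices) and `correlation`.
#' @export
similarity_analysis <- function(table, fc_threshold = 2, p_threshold = 0.05,
                                denominator_floor = 0.25) {
  expr <- table$expr; samples <- table$samples
  de <- differential_genes(expr, samples, fc_threshold, p_threshold)
  m <- population_means(expr, samples)
  s <- similarity_index(m[, "SPR"], m[, "DP"], m[, "SPF"], denominator_floor)
  is_de <- rownames(expr) %in% de$union
  bins_de <- bin_similarity(s[is_de])
  all_bins <- rep(NA_character_, nrow(expr))
  all_bins[is_de] <- as.character(bins_de$bin)
  list(
    per_gene = data.frame(gene_id = rownames(expr), de = is_de,
                          similarity = unname(s), bin = all_bins,
                          stringsAsFactors = FALSE),
    de = de,
    fractions = bins_de$fractions,
    correlation = population_correlation(expr, samples,
                                         min_genes = min(50, nrow(expr)))
  )
}
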