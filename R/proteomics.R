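#' Protein abundance matrix
#'
#' Log2 label-free quantification (LFQ) intensities, proteins x samples,
#' with a sample-to-condition map and the usual shotgun-proteomics QC flags
#' (reverse-database hit, potential contaminant, only identified by site).
#' Missing values are `NA`.
#'
#' @param exprs numeric matrix of log2 LFQ intensities (rows = proteins,
#'   columns = samples); `NA` marks invalid values.
#' @param condition factor or character of length `ncol(exprs)` assigning
#'   each sample to exactly one condition; at least two conditions.
#' @param protein_id,gene_symbol identifiers per row.
#' @param reverse,contaminant,only_site logical QC flags per row.
#' @param presence_absence logical per row: quantified in only one
#'   condition (filled by [filter_and_impute()]).
#' @return An `abundance_matrix` object.
#' @export
abundance_matrix <- function(exprs, condition,
                             protein_id = rownames(exprs),
                             gene_symbol = protein_id,
                             reverse = FALSE, contaminant = FALSE,
                             only_site = FALSE, presence_absence = FALSE) {
  exprs <- as.matrix(exprs)
  condition <- factor(condition)
  if (length(condition) != ncol(exprs))
    stop("one condition per sample required", call. = FALSE)
  if (nlevels(condition) < 2L)
    stop("need at least two conditions", call. = FALSE)
  if (anyNA(condition))
    stop("missing condition assignment", call. = FALSE)
  if (is.null(protein_id)) protein_id <- paste0("P", seq_len(nrow(exprs)))
  if (anyDuplicated(protein_id))
    stop("duplicate protein ids", call. = FALSE)
  rownames(exprs) <- protein_id
  rec <- function(x) if (length(x) == 1L) rep(as.logical(x), nrow(exprs)) else as.logical(x)
  structure(list(exprs = exprs, condition = condition,
                 protein_id = as.character(protein_id),
                 gene_symbol = as.character(gene_symbol),
                 reverse = rec(reverse), contaminant = rec(contaminant),
                 only_site = rec(only_site),
                 presence_absence = rec(presence_absence)),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("Abundance matrix: %d proteins x %d samples (%s)\n",
              nrow(x$exprs), ncol(x$exprs),
              paste(sprintf("%s n=%d", levels(x$condition),
                            table(x$condition)), collapse = ", ")))
  cat(sprintf("  %.1f%% missing; flags: %d reverse, %d contaminant, %d only-site\n",
              100 * mean(is.na(x$exprs)), sum(x$reverse), sum(x$contaminant),
              sum(x$only_site)))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$exprs)

# subset rows, keeping all per-protein vectors in step
am_subset <- function(m, keep) {
  m$exprs <- m$exprs[keep, , drop = FALSE]
  for (f in c("protein_id", "gene_symbol", "reverse", "contaminant",
              "only_site", "presence_absence"))
    m[[f]] <- m[[f]][keep]
  m
}

#' Read a proteinGroups-style TSV
#'
#' Parses the MaxQuant proteinGroups dialect: one row per protein group,
#' raw intensities in `LFQ intensity <sample>` columns, flag columns
#' `Reverse`, `Potential contaminant`, `Only identified by site` marked
#' with `"+"`. Intensities are log2-transformed; zeros and blanks become
#' missing values.
#'
#' @param path TSV file path.
#' @param condition named character/factor: names are sample names (the
#'   suffix of the LFQ columns), values the condition labels.
#' @return An [abundance_matrix()].
#' @export
load_protein_groups <- function(path, condition) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lfq_cols <- grep("^LFQ intensity ", names(d), value = TRUE)
  if (length(lfq_cols) == 0L)
    stop("no 'LFQ intensity <sample>' columns found", call. = FALSE)
  samples <- sub("^LFQ intensity ", "", lfq_cols)
  if (!all(samples %in% names(condition)))
    stop("missing condition assignment for sample(s): ",
         paste(setdiff(samples, names(condition)), collapse = ", "),
         call. = FALSE)
  x <- as.matrix(d[lfq_cols])
  mode(x) <- "numeric"
  x[!is.finite(x) | x <= 0] <- NA        # zero / blank intensity = invalid
  x <- log2(x)
  colnames(x) <- samples
  flag <- function(col) {
    if (!col %in% names(d)) return(rep(FALSE, nrow(d)))
    v <- trimws(as.character(d[[col]]))
    !is.na(v) & v == "+"
  }
  abundance_matrix(
    x, condition = unname(condition[samples]),
    protein_id = if ("Protein IDs" %in% names(d)) d[["Protein IDs"]] else NULL,
    gene_symbol = if ("Gene names" %in% names(d)) d[["Gene names"]]
                  else if ("Protein IDs" %in% names(d)) d[["Protein IDs"]] else NULL,
    reverse = flag("Reverse"), contaminant = flag("Potential contaminant"),
    only_site = flag("Only identified by site"))
}

#' @rdname load_protein_groups
#' @param m an [abundance_matrix()].
#' @export
write_protein_groups <- function(m, path) {
  stopifnot(inherits(m, "abundance_matrix"))
  raw <- 2^m$exprs
  raw[is.na(raw)] <- 0
  colnames(raw) <- paste("LFQ intensity", colnames(m$exprs))
  d <- data.frame(`Protein IDs` = m$protein_id, `Gene names` = m$gene_symbol,
                  check.names = FALSE)
  d <- cbind(d, as.data.frame(raw, check.names = FALSE))
  d[["Reverse"]] <- ifelse(m$reverse, "+", "")
  d[["Potential contaminant"]] <- ifelse(m$contaminant, "+", "")
  d[["Only identified by site"]] <- ifelse(m$only_site, "+", "")
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quality filtering and missing-value handling
#'
#' Removes reverse-database, contaminant and only-identified-by-site rows,
#' then applies the study's valid-value rule. In `"presence_absence"` mode
#' (lesioned-vs-unlesioned convention) any row with one or more invalid
#' values is dropped, EXCEPT rows that are fully missing in exactly one
#' condition and fully valid in the other: these are retained, flagged as
#' presence/absence proteins, and their missing side is imputed from a
#' down-shifted normal distribution per sample,
#' \eqn{N(\bar{x}_s - \mathrm{shift}\,\sigma_s,\ (\mathrm{width}\,\sigma_s)^2)}
#' (Perseus-style defaults shift = 1.8, width = 0.3), with a seeded RNG.
#' In `"strict"` mode every row with any invalid value is dropped.
#'
#' @param m an [abundance_matrix()].
#' @param rule `"presence_absence"` (default) or `"strict"`.
#' @param shift,width down-shifted-imputation parameters in sample-SD units.
#' @param seed RNG seed for the imputation draw.
#' @return A filtered [abundance_matrix()]; imputed rows carry
#'   `presence_absence = TRUE`.
#' @export
filter_and_impute <- function(m, rule = c("presence_absence", "strict"),
                              shift = 1.8, width = 0.3, seed = 1) {
  stopifnot(inherits(m, "abundance_matrix"))
  rule <- match.arg(rule)
  m <- am_subset(m, !(m$reverse | m$contaminant | m$only_site))
  conds <- levels(m$condition)
  valid <- !is.na(m$exprs)
  n_valid <- vapply(conds, function(cc)
    rowSums(valid[, m$condition == cc, drop = FALSE]), numeric(nrow(m$exprs)))
  n_total <- vapply(conds, function(cc) sum(m$condition == cc), numeric(1))
  all_valid <- rowSums(valid) == ncol(valid)
  if (rule == "strict") return(am_subset(m, all_valid))

  full <- sweep(n_valid, 2, n_total, `==`)      # fully valid per condition
  empty <- n_valid == 0                          # fully missing per condition
  pa <- unname(rowSums(full) == length(conds) - 1L & rowSums(empty) == 1L)
  keep <- all_valid | pa
  m <- am_subset(m, keep)
  m$presence_absence <- pa[keep]
  if (any(m$presence_absence)) {
    m$exprs <- with_seed(sub_seed(seed, "impute"), {
      x <- m$exprs
      for (s in seq_len(ncol(x))) {
        mu <- mean(x[, s], na.rm = TRUE)
        sd_s <- stats::sd(x[, s], na.rm = TRUE)
        if (!is.finite(sd_s)) sd_s <- 0   # degenerate tiny tables
        miss <- which(is.na(x[, s]) & m$presence_absence)
        if (length(miss))
          x[miss, s] <- stats::rnorm(length(miss), mu - shift * sd_s, width * sd_s)
      }
      x
    })
  }
  m
}

#' s0-moderated SAM test statistic
#'
#' \eqn{t_{s_0} = (\bar{x}_B - \bar{x}_A) / (s + s_0)} where
#' \eqn{s = s_p \sqrt{1/n_A + 1/n_B}} is the pooled two-sample standard
#' error and \eqn{s_0} a small positive offset damping low-variance
#' artifacts. With \eqn{s_0 = 0} this is exactly the classical pooled
#' two-sample t statistic.
#'
#' @param a,b numeric vectors (each n >= 2) — or matrices with proteins in
#'   rows for the vectorized row-wise form.
#' @param s0 denominator offset (study default 0.1).
#' @return The statistic (scalar or per-row vector).
#' @export
#' @examples
#' sam_statistic(c(10, 11, 12), c(13, 14, 15), s0 = 0.1)  # 3.273
sam_statistic <- function(a, b, s0 = 0.1) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2", call. = FALSE)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2); vb <- rowSums((b - mb)^2)
  sp <- sqrt((va + vb) / (na + nb - 2))
  s <- sp * sqrt(1 / na + 1 / nb)
  out <- (mb - ma) / (s + s0)
  if (length(out) == 1L) out[[1]] else out
}

# all distinct balanced label splits as a matrix of column indices for "group A"
enumerate_splits <- function(n, na) {
  utils::combn(n, na)
}

#' SAM-style permutation FDR
#'
#' Computes the observed \eqn{|t_{s_0}|} per protein, re-computes it under
#' label permutations (exhaustive when the number of distinct splits is at
#' most `n_perm`, otherwise a seeded random subset), and estimates, for each
#' threshold, \eqn{FDR = \widehat{\#\mathrm{false}} / \#\mathrm{called}}
#' with the permutation call count summarized across permutations.
#' Per-protein q-values are the smallest FDR at which the protein is
#' called.
#'
#' The observed labeling — and, for balanced designs, its mirror image,
#' which yields identical \eqn{|t_{s_0}|} — is excluded from the
#' permutation null. The call count is summarized by its mean by default;
#' the Tusher-style median variant (`estimator = "median"`) is available
#' but is markedly anticonservative on small balanced designs (see the
#' methods vignette), so the mean is the default.
#'
#' @param m an [abundance_matrix()], or a numeric matrix with `labels`.
#' @param labels condition per column (ignored for `abundance_matrix`
#'   input). Exactly two conditions.
#' @param s0 denominator offset.
#' @param n_perm maximum number of permutations.
#' @param seed RNG seed for the random-subset case.
#' @param fdr significance threshold on the q-value (default 0.1).
#' @param estimator `"mean"` (default) or `"median"` permutation call count.
#' @return data.frame with `protein_id`, `log2fc` (second condition level
#'   minus first), `t_s0`, `qvalue`, `significant`, plus attributes
#'   `n_splits_total` (distinct balanced splits), `n_permutations` (splits
#'   used in the null) and `exhaustive`.
#' @export
permutation_fdr <- function(m, labels = NULL, s0 = 0.1, n_perm = 1000,
                            seed = 1, fdr = 0.1,
                            estimator = c("mean", "median")) {
  estimator <- match.arg(estimator)
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  if (inherits(m, "abundance_matrix")) {
    x <- m$exprs; labels <- m$condition; ids <- m$protein_id
  } else {
    x <- as.matrix(m)
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("P", seq_len(nrow(x)))
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two conditions required", call. = FALSE)
  ia <- which(labels == levels(labels)[1]); ib <- which(labels == levels(labels)[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("need >= 2 samples per condition", call. = FALSE)
  if (anyNA(x))
    stop("missing values present; run filter_and_impute() first", call. = FALSE)

  t_obs <- sam_statistic(x[, ia, drop = FALSE], x[, ib, drop = FALSE], s0)
  log2fc <- rowMeans(x[, ib, drop = FALSE]) - rowMeans(x[, ia, drop = FALSE])

  n <- ncol(x)
  splits <- enumerate_splits(n, length(ia))
  n_splits_total <- ncol(splits)
  # drop the observed labeling and (balanced case) its mirror: both
  # reproduce the observed |t| and would contaminate the null
  obs <- sort(ia)
  is_obs <- apply(splits, 2, function(s)
    identical(sort(s), obs) ||
      identical(sort.int(setdiff(seq_len(n), s)), obs))
  splits <- splits[, !is_obs, drop = FALSE]
  exhaustive <- ncol(splits) <= n_perm
  if (!exhaustive) {
    splits <- with_seed(sub_seed(seed, "perm"), {
      splits[, sample.int(ncol(splits), n_perm), drop = FALSE]
    })
  }
  abs_perm <- apply(splits, 2, function(idx) {
    abs(sam_statistic(x[, idx, drop = FALSE], x[, -idx, drop = FALSE], s0))
  })  # proteins x permutations

  # threshold sweep at the observed |t| values (descending)
  a_obs <- abs(t_obs)
  ord <- order(a_obs, decreasing = TRUE)
  thr <- a_obs[ord]
  n_called <- seq_along(thr)
  # permutation call counts >= each threshold, per permutation
  perm_counts <- vapply(seq_len(ncol(abs_perm)), function(j) {
    sv <- sort(abs_perm[, j], decreasing = TRUE)
    findInterval(-thr, -sv)     # counts >= thr (descending trick)
  }, integer(length(thr)))
  if (is.null(dim(perm_counts))) perm_counts <- matrix(perm_counts, nrow = length(thr))
  false_est <- apply(perm_counts, 1, if (estimator == "median") stats::median else mean)
  fdr_at_thr <- pmin(false_est / n_called, 1)
  # q-value: smallest FDR over thresholds at or below this protein's |t|
  q_sorted <- rev(cummin(rev(fdr_at_thr)))
  qvalue <- numeric(length(t_obs))
  qvalue[ord] <- q_sorted
  out <- data.frame(protein_id = ids, log2fc = log2fc, t_s0 = t_obs,
                    qvalue = qvalue, significant = qvalue < fdr,
                    row.names = NULL)
  attr(out, "n_splits_total") <- n_splits_total
  attr(out, "n_permutations") <- ncol(splits)
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Regulation class from fold change and significance
#'
#' `up` iff FDR-significant and \eqn{\log_2 FC \ge \log_2(\mathrm{fc})};
#' `down` iff significant and \eqn{\log_2 FC \le -\log_2(\mathrm{fc})};
#' otherwise `ns`. The linear-scale threshold (default 1.3) is applied on
#' the log2 scale, the standard Perseus convention for log-transformed LFQ
#' data.
#'
#' @param log2fc log2 fold changes.
#' @param significant logical FDR calls.
#' @param fc_threshold linear fold-change threshold (> 1).
#' @return factor with levels `up`, `down`, `ns`.
#' @export
classify_regulation <- function(log2fc, significant, fc_threshold = 1.3) {
  if (fc_threshold <= 1) stop("`fc_threshold` must be > 1", call. = FALSE)
  lt <- log2(fc_threshold)
  cls <- ifelse(significant & log2fc >= lt, "up",
         ifelse(significant & log2fc <= -lt, "down", "ns"))
  factor(cls, levels = c("up", "down", "ns"))
}

#' Differential abundance pipeline
#'
#' Convenience wrapper: [filter_and_impute()] then [permutation_fdr()] then
#' [classify_regulation()], with the study defaults (s0 = 0.1, FDR < 0.1,
#' |FC| >= 1.3).
#'
#' @inheritParams permutation_fdr
#' @inheritParams filter_and_impute
#' @inheritParams classify_regulation
#' @return A `DiffResult` data.frame: `protein_id`, `gene_symbol`,
#'   `log2fc`, `t_s0`, `qvalue`, `significant`, `class`,
#'   `presence_absence`.
#' @export
diff_abundance <- function(m, rule = "presence_absence", s0 = 0.1,
                           n_perm = 1000, seed = 1, fdr = 0.1,
                           fc_threshold = 1.3) {
  stopifnot(inherits(m, "abundance_matrix"))
  mf <- filter_and_impute(m, rule = rule, seed = seed)
  res <- permutation_fdr(mf, s0 = s0, n_perm = n_perm, seed = seed, fdr = fdr)
  res$gene_symbol <- mf$gene_symbol
  res$class <- classify_regulation(res$log2fc, res$significant, fc_threshold)
  res$presence_absence <- mf$presence_absence
  res[c("protein_id", "gene_symbol", "log2fc", "t_s0", "qvalue",
        "significant", "class", "presence_absence")]
}

#' Row-wise Z-score standardization
#'
#' Each row is centered to mean 0 and scaled to sample standard deviation 1
#' (the heatmap convention).
#'
#' @param x numeric matrix with non-constant rows.
#' @return Matrix of identical shape.
#' @export
zscore_rows <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  if (any(s == 0)) stop("constant row: Z-score undefined", call. = FALSE)
  (x - mu) / s
}

#' Matrisome annotation join
#'
#' Left-joins protein/gene identifiers against a matrisome list (division:
#' core matrisome / matrisome-associated / putative; category; mammalian
#' ortholog symbol). Unmatched identifiers are flagged non-matrisome.
#'
#' @param ids character identifiers.
#' @param annotation data.frame with columns `gene`, `division`, `category`
#'   and optionally `mammalian_ortholog`; one row per gene.
#' @param normalizer `"exact"` or `"case_insensitive"` symbol matching.
#' @return data.frame: `id`, `matrisome` (logical), `division`, `category`,
#'   `mammalian_ortholog`.
#' @export
annotate_matrisome <- function(ids, annotation,
                               normalizer = c("exact", "case_insensitive")) {
  normalizer <- match.arg(normalizer)
  req <- c("gene", "division", "category")
  if (!all(req %in% names(annotation)))
    stop("annotation needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  key <- if (normalizer == "case_insensitive") tolower(annotation$gene) else annotation$gene
  if (anyDuplicated(key))
    stop("duplicate annotation keys", call. = FALSE)
  lookup <- if (normalizer == "case_insensitive") tolower(ids) else ids
  i <- match(lookup, key)
  data.frame(
    id = ids, matrisome = !is.na(i),
    division = ifelse(is.na(i), NA_character_, annotation$division[i]),
    category = ifelse(is.na(i), NA_character_, annotation$category[i]),
    mammalian_ortholog = if ("mammalian_ortholog" %in% names(annotation))
      ifelse(is.na(i), NA_character_, annotation$mammalian_ortholog[i])
    else NA_character_,
    row.names = NULL)
}

#' Cross-species regulation screen
#'
#' Buckets ortholog-matched proteins by their regulation class in two
#' differential-abundance results (e.g., zebrafish vs rat spinal lesion):
#' `A_up_B_down_or_ns` (enriched in A but down/not significant in B),
#' `A_down_or_ns_B_up` (the converse), `concordant` (identical class), or
#' `other`. The buckets partition the matched set. Many-to-many ortholog
#' rows are resolved to the representative with the largest observed
#' \eqn{|t_{s_0}|}, with a message.
#'
#' @param res_a,res_b `DiffResult` data.frames from [diff_abundance()] (need
#'   `class`, `t_s0` and the key column).
#' @param ortholog_map data.frame with columns `a`, `b`: identifier pairs
#'   keyed on `key`.
#' @param key column of the results used for matching (default
#'   `"gene_symbol"`).
#' @return data.frame with one row per resolved pair: `a`, `b`, `class_a`,
#'   `class_b`, `bucket`; bucket counts as attribute `counts`.
#' @export
cross_species_screen <- function(res_a, res_b, ortholog_map,
                                 key = "gene_symbol") {
  stopifnot(all(c("a", "b") %in% names(ortholog_map)))
  pick <- function(res, idcol, wanted) {
    res <- res[res[[idcol]] %in% wanted, , drop = FALSE]
    if (anyDuplicated(res[[idcol]])) {
      res <- res[order(-abs(res$t_s0)), , drop = FALSE]
      res <- res[!duplicated(res[[idcol]]), , drop = FALSE]
      message("many-to-many mapping resolved by highest |t_s0| representative")
    }
    res
  }
  ra <- pick(res_a, key, ortholog_map$a)
  rb <- pick(res_b, key, ortholog_map$b)
  ia <- match(ortholog_map$a, ra[[key]])
  ib <- match(ortholog_map$b, rb[[key]])
  ok <- !is.na(ia) & !is.na(ib)
  ca <- as.character(ra$class[ia[ok]])
  cb <- as.character(rb$class[ib[ok]])
  bucket <- ifelse(ca == "up" & cb %in% c("down", "ns"), "A_up_B_down_or_ns",
            ifelse(ca %in% c("down", "ns") & cb == "up", "A_down_or_ns_B_up",
            ifelse(ca == cb, "concordant", "other")))
  out <- data.frame(a = ortholog_map$a[ok], b = ortholog_map$b[ok],
                    class_a = ca, class_b = cb,
                    bucket = factor(bucket,
                                    levels = c("A_up_B_down_or_ns",
                                               "A_down_or_ns_B_up",
                                               "concordant", "other")),
                    row.names = NULL)
  attr(out, "counts") <- table(out$bucket)
  out
}

#' Over-representation analysis (hypergeometric + Bonferroni)
#'
#' One-sided hypergeometric upper-tail p-value per gene set, Bonferroni
#' correction over the tested sets, significance at adjusted p <= 0.05.
#'
#' @param foreground character vector of hit identifiers (must be a subset
#'   of `background`).
#' @param background character vector defining the tested universe.
#' @param gene_sets named list of identifier vectors.
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @return data.frame: `set`, `set_size` (in background), `overlap`,
#'   `p`, `p_bonferroni`, `significant`.
#' @export
ora_enrichment <- function(foreground, background, gene_sets, alpha = 0.05) {
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  foreground <- unique(foreground); background <- unique(background)
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background", call. = FALSE)
  N <- length(background); n <- length(foreground)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    K <- length(set)
    k <- length(intersect(set, foreground))
    p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out$significant <- out$p_bonferroni <= alpha
  out
}
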