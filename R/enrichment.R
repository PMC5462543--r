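#' Count HPPGs uniquely shared between a lineage pair
#'
#' Restricts the presence matrix to HPPGs present in exactly two of the
#' five watched lineages (diatoms including dinotoms, hypogyristea,
#' chrysista, haptophytes, cryptomonads) and counts those meeting the
#' mode's thresholds for the named pair: `majority+any` requires a
#' majority of the first lineage's sub-categories and at least one
#' sub-category of the second; `majority+majority` requires majorities of
#' both. Majorities are inclusive fractions of the number of
#' sub-categories per lineage.
#'
#' @param presence integer matrix: HPPGs x sub-categories (counts of
#'   members).
#' @param pair character vector of two watched lineage names, the first
#'   being the majority-side lineage in `majority+any` mode.
#' @param mode `"majority+any"` or `"majority+majority"`.
#' @param lineage_subcats named list: watched lineage -> its sub-category
#'   columns. A majority of n sub-categories is `floor(n/2) + 1` (2 of 3,
#'   3 of 5), matching the inclusive >=2/3 and >=3/5 rules.
#' @return integer count.
#' @export
count_unique_shared <- function(presence, pair,
                                mode = c("majority+any",
                                         "majority+majority"),
                                lineage_subcats) {
  mode <- match.arg(mode)
  stopifnot(length(pair) == 2L, all(pair %in% names(lineage_subcats)))
  lin_present <- vapply(lineage_subcats, function(subs) {
    rowSums(presence[, subs, drop = FALSE] >= 1L) >= 1L
  }, logical(nrow(presence)))
  if (is.null(dim(lin_present)))
    lin_present <- matrix(lin_present, nrow = 1L,
                          dimnames = list(NULL, names(lineage_subcats)))
  exactly_two <- rowSums(lin_present) == 2L
  need <- function(lin, majority) {
    subs <- lineage_subcats[[lin]]
    k <- rowSums(presence[, subs, drop = FALSE] >= 1L)
    if (majority) k >= (length(subs) %/% 2L + 1L) else k >= 1L
  }
  ok <- exactly_two & lin_present[, pair[1L]] & lin_present[, pair[2L]] &
    need(pair[1L], TRUE) &
    need(pair[2L], mode == "majority+majority")
  sum(ok)
}

#' Corrected expected fraction of HPPGs shared by one lineage pair
#'
#' Implements the published expectation correction for uniquely shared
#' HPPGs: the raw expected fraction for a pair is the product of the two
#' lineages' involvement proportions, and the same product is the mass
#' mis-allocated to single-lineage sharing, so the corrected fraction is
#' `p_i * p_j / (1 - p_i * p_j)`. With both proportions at one half, the
#' raw quarter is multiplied by four-thirds to give one-third.
#'
#' @param p_i,p_j involvement proportions of the two lineages (fraction of
#'   uniquely shared HPPGs involving each lineage).
#' @return corrected expected fraction.
#' @export
expected_pair_fraction <- function(p_i, p_j) {
  raw <- p_i * p_j
  if (any(raw >= 1)) stop("degenerate proportions")
  raw / (1 - raw)
}

#' Corrected expected counts of uniquely shared HPPGs
#'
#' From observed pair counts, derives per-lineage involvement proportions
#' (the fraction of uniquely shared HPPGs involving each lineage) and the
#' per-pair corrected fractions of [expected_pair_fraction()]. Because the
#' per-pair corrections do not form a probability distribution, the
#' corrected fractions are used as weights and rescaled so that the
#' cross-pair expectations sum exactly to the observed cross-pair total
#' (they coincide with the per-pair values in symmetric designs).
#'
#' @param pair_counts square symmetric-intent matrix (upper triangle used)
#'   or data.frame of `lineage_a`, `lineage_b`, `count`.
#' @return data.frame of `lineage_a`, `lineage_b`, `observed`, `expected`,
#'   `corrected_fraction` (the per-pair value before rescaling), with
#'   attributes `proportions` and `total`.
#' @export
expected_unique_shared <- function(pair_counts) {
  if (is.data.frame(pair_counts)) {
    lins <- sort(unique(c(pair_counts$lineage_a, pair_counts$lineage_b)))
    m <- matrix(0, length(lins), length(lins), dimnames = list(lins, lins))
    for (i in seq_len(nrow(pair_counts))) {
      a <- pair_counts$lineage_a[i]; b <- pair_counts$lineage_b[i]
      m[a, b] <- m[a, b] + pair_counts$count[i]
      if (a != b) m[b, a] <- m[b, a] + pair_counts$count[i]
    }
  } else {
    m <- pair_counts
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    lins <- rownames(m)
  }
  if (length(lins) < 2L) stop("no cross pairs: need at least two lineages")
  total <- sum(m[upper.tri(m)])
  if (total == 0) stop("no cross pairs: all pair counts are zero")
  involvement <- rowSums(m) - diag(m)
  p <- involvement / total # fraction of uniquely shared HPPGs involving i
  rows <- list()
  cmb <- utils::combn(lins, 2L)
  for (k in seq_len(ncol(cmb))) {
    a <- cmb[1L, k]; b <- cmb[2L, k]
    rows[[k]] <- data.frame(
      lineage_a = a, lineage_b = b, observed = m[a, b],
      corrected_fraction = expected_pair_fraction(p[[a]], p[[b]]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$expected <- total * out$corrected_fraction /
    sum(out$corrected_fraction)
  out <- out[, c("lineage_a", "lineage_b", "observed", "expected",
                 "corrected_fraction")]
  attr(out, "proportions") <- p
  attr(out, "total") <- total
  out
}

#' Percentage share of a count within a total
#'
#' Convenience used when re-expressing count pairs as the rounded
#' percentages a report would print.
#'
#' @param count,total non-negative counts (`total` > 0).
#' @param digits decimal places of the printed percentage.
#' @return numeric percentage.
#' @export
percent_share <- function(count, total, digits = 0) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, digits)
}

#' Two-cell goodness-of-fit chi-squared against an expected count
#'
#' Compares an observed category count to its expectation within a total:
#' cells `[observed, total - observed]` against `[expected,
#' total - expected]`, one degree of freedom, no continuity correction.
#'
#' @param observed observed count.
#' @param expected expected count (> 0).
#' @param total total count (>= observed; > expected).
#' @param label optional label.
#' @param alpha significance threshold.
#' @return list of class `enrichment_result`: `label`, `observed`,
#'   `expected`, `statistic`, `p`, `significant`.
#' @export
chi_squared_obs_exp <- function(observed, expected, total,
                                label = NA_character_, alpha = 0.05) {
  if (expected <= 0) stop("expected must be positive")
  if (total < observed) stop("total smaller than observed")
  if (total <= expected) stop("total must exceed expected")
  stat <- (observed - expected)^2 / expected +
    (observed - expected)^2 / (total - expected)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  out <- list(label = label, observed = observed, expected = expected,
              statistic = stat, p = p, significant = p < alpha)
  class(out) <- "enrichment_result"
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: observed %.4g, expected %.4g, X2 = %.4g, p = %.4g%s\n",
              if (is.na(x$label)) "enrichment" else x$label,
              x$observed, x$expected, x$statistic, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Plastid-targeting enrichment by evolutionary origin
#'
#' For each origin, the expected number of plastid-targeted families is
#' the total number of plastid-targeted families distributed in proportion
#' to the origin's share of all families (a random assortment of targeting
#' over origins); a two-cell chi-squared flags origins carrying
#' significantly more (or fewer) plastid-targeted families than expected.
#' Expectations sum exactly to the total plastid-targeted count.
#'
#' @param families data.frame with columns `origin` and `plastid` (logical
#'   consensus targeting call).
#' @param alpha significance threshold.
#' @return data.frame per origin: `origin`, `n_families`, `observed`,
#'   `expected`, `statistic`, `p`, `significant`.
#' @export
targeting_enrichment <- function(families, alpha = 0.05) {
  stopifnot(all(c("origin", "plastid") %in% names(families)))
  n_total <- nrow(families)
  n_plastid <- sum(families$plastid)
  rows <- lapply(sort(unique(families$origin)), function(o) {
    sel <- families$origin == o
    expected <- n_plastid * sum(sel) / n_total
    observed <- sum(families$plastid & sel)
    if (expected <= 0 || n_plastid <= expected || n_plastid == 0) {
      return(data.frame(origin = o, n_families = sum(sel),
                        observed = observed, expected = expected,
                        statistic = NA_real_, p = NA_real_,
                        significant = FALSE, stringsAsFactors = FALSE))
    }
    r <- chi_squared_obs_exp(observed, expected, n_plastid, label = o,
                             alpha = alpha)
    data.frame(origin = o, n_families = sum(sel), observed = observed,
               expected = expected, statistic = r$statistic, p = r$p,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Functional-category enrichment of a subset against a background
#'
#' Per category, the expected subset count is the subset total times the
#' background proportion; a two-cell chi-squared flags categories at
#' `p < alpha`. Categories absent from the background are skipped with a
#' message.
#'
#' @param subset_counts,background_counts named integer vectors of
#'   category counts.
#' @param alpha significance threshold.
#' @return data.frame per category: `category`, `observed`, `expected`,
#'   `statistic`, `p`, `significant`.
#' @export
category_enrichment <- function(subset_counts, background_counts,
                                alpha = 0.05) {
  missing <- setdiff(names(subset_counts), names(background_counts))
  if (length(missing))
    message("categories absent from background skipped: ",
            paste(missing, collapse = ", "))
  cats <- intersect(names(subset_counts), names(background_counts))
  n_sub <- sum(subset_counts[cats])
  n_bg <- sum(background_counts[cats])
  rows <- lapply(cats, function(cc) {
    expected <- n_sub * background_counts[[cc]] / n_bg
    observed <- subset_counts[[cc]]
    if (expected <= 0 || expected >= n_sub)
      return(data.frame(category = cc, observed = observed,
                        expected = expected, statistic = NA_real_,
                        p = NA_real_, significant = FALSE,
                        stringsAsFactors = FALSE))
    r <- chi_squared_obs_exp(observed, expected, n_sub, label = cc,
                             alpha = alpha)
    data.frame(category = cc, observed = observed, expected = expected,
               statistic = r$statistic, p = r$p, significant = r$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concordance of evolutionary origin between biochemical neighbours
#'
#' Drops pairs with an unresolved member, counts pairs whose two proteins
#' share the same origin, and compares against the expectation under
#' random assortment: the number of pairs times the sum of squared origin
#' proportions among proteins appearing in pairs (counted with
#' multiplicity).
#'
#' @param pairs data.frame with columns `a` and `b` (protein ids).
#' @param origin_map named character vector protein -> origin
#'   (`"unresolved"`/NA members drop the pair).
#' @param alpha significance threshold.
#' @return an `enrichment_result` with extra fields `n_pairs`,
#'   `proportions`.
#' @export
neighbour_origin_concordance <- function(pairs, origin_map, alpha = 0.05) {
  oa <- origin_map[pairs$a]; ob <- origin_map[pairs$b]
  ok <- !is.na(oa) & !is.na(ob) & oa != "unresolved" & ob != "unresolved"
  oa <- oa[ok]; ob <- ob[ok]
  n <- length(oa)
  if (n < 2L) stop("fewer than two resolved pairs")
  q <- table(c(oa, ob)) / (2 * n)
  expected <- n * sum(q^2)
  observed <- sum(oa == ob)
  if (observed == n && expected == n) {
    out <- list(label = "neighbour concordance", observed = observed,
                expected = expected, statistic = 0, p = 1,
                significant = FALSE)
    class(out) <- "enrichment_result"
  } else {
    out <- chi_squared_obs_exp(observed, expected, n,
                               label = "neighbour concordance",
                               alpha = alpha)
  }
  out$n_pairs <- n
  out$proportions <- q
  out
}

#' Coexpression structure by evolutionary origin
#'
#' Pearson correlations for every gene pair, grouped into origin-pair
#' classes; per class the mean correlation is reported. For each origin,
#' a one-way ANOVA compares the within-origin correlations against each
#' origin-other class (a single omnibus F-test per origin over those
#' classes). Pairs of correlations share genes and are not independent,
#' so these p-values are descriptive rather than exact. Constant
#' expression vectors are excluded with a message.
#'
#' @param expression numeric matrix, genes x conditions.
#' @param gene_to_origin named character vector gene -> origin.
#' @param alpha significance threshold.
#' @return list: `class_means` (data.frame origin-pair class means),
#'   `anova` (data.frame per origin: `origin`, `f`, `p`, `significant`),
#'   `correlations` (long data.frame of pairs).
#' @export
coexpression_by_origin <- function(expression, gene_to_origin,
                                   alpha = 0.05) {
  genes <- intersect(rownames(expression), names(gene_to_origin))
  expression <- expression[genes, , drop = FALSE]
  sds <- apply(expression, 1L, stats::sd)
  if (any(sds == 0)) {
    message("excluding ", sum(sds == 0), " constant expression vector(s)")
    expression <- expression[sds > 0, , drop = FALSE]
    genes <- rownames(expression)
  }
  origin <- gene_to_origin[genes]
  if (min(table(origin)) < 2L)
    stop("need at least two genes per origin class")
  cm <- stats::cor(t(expression))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  long <- data.frame(
    gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
    r = cm[idx],
    class = paste(pmin(origin[idx[, 1L]], origin[idx[, 2L]]),
                  pmax(origin[idx[, 1L]], origin[idx[, 2L]]), sep = "-"),
    origin_a = origin[idx[, 1L]], origin_b = origin[idx[, 2L]],
    stringsAsFactors = FALSE)
  class_means <- stats::aggregate(r ~ class, data = long, FUN = mean)
  anova_rows <- lapply(sort(unique(origin)), function(o) {
    sel <- long$origin_a == o | long$origin_b == o
    d <- long[sel, , drop = FALSE]
    d$grp <- ifelse(d$origin_a == o & d$origin_b == o, paste0(o, "-", o),
                    d$class)
    if (length(unique(d$grp)) < 2L || min(table(d$grp)) < 2L)
      return(data.frame(origin = o, f = NA_real_, p = NA_real_,
                        significant = FALSE, stringsAsFactors = FALSE))
    fit <- stats::aov(r ~ grp, data = d)
    s <- summary(fit)[[1L]]
    data.frame(origin = o, f = s[["F value"]][1L], p = s[["Pr(>F)"]][1L],
               significant = s[["Pr(>F)"]][1L] <= alpha,
               stringsAsFactors = FALSE)
  })
  list(class_means = class_means, anova = do.call(rbind, anova_rows),
       correlations = long)
}
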