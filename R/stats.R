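# Species-comparison statistics: one-way ANOVA with Tukey HSD, correlation
# and regression of retention against wettability/surface energy, and
# k-means clustering of species into capacity tiers.

check_grouped <- function(values, group) {
  stopifnot(length(values) == length(group), is.numeric(values))
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) {
    ld_abort("at least 2 species are required", "leafdepo_validation_error")
  }
  n <- table(droplevels(group))
  if (any(n < 2)) {
    ld_abort(paste0("species with < 2 replicates: ",
                    paste(names(n)[n < 2], collapse = ", ")),
             "leafdepo_validation_error")
  }
  droplevels(group)
}

#' One-way fixed-effects ANOVA across species
#'
#' @param values Numeric outcome (e.g. batch-level densities or
#'   efficiencies), one value per replicate.
#' @param group Species identifier per replicate; every species needs at
#'   least 2 replicates.
#' @return Tibble with `f`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(values, group) {
  group <- check_grouped(values, group)
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  tibble::tibble(
    f = tab$`F value`[1],
    p = tab$`Pr(>F)`[1],
    df_between = tab$Df[1],
    df_within = tab$Df[2]
  )
}

#' Tukey HSD pairwise species comparisons
#'
#' Studentized-range based all-pairs comparison following a one-way ANOVA,
#' at family-wise level `alpha`.
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise error rate, default 0.05.
#' @return Tibble per pair: `pair`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(values, group, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  group <- check_grouped(values, group)
  fit <- stats::aov(values ~ group)
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  tibble::tibble(
    pair = rownames(hsd),
    diff = unname(hsd[, "diff"]),
    lwr = unname(hsd[, "lwr"]),
    upr = unname(hsd[, "upr"]),
    p_adj = unname(hsd[, "p adj"]),
    significant = unname(hsd[, "p adj"] < alpha)
  )
}

#' Correlation between a species trait and PM retention
#'
#' Pearson (default) or Spearman correlation with a two-sided test, plus
#' the least-squares regression slope of y on x.
#'
#' @param x,y Paired per-species values, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble with `r`, `p`, `slope`, `intercept`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    ld_abort("at least 3 complete pairs are required", "leafdepo_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    ld_abort("zero variance in x or y; correlation undefined",
             "leafdepo_numeric_error")
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  fit <- stats::lm(y ~ x)
  tibble::tibble(
    r = unname(ct$estimate),
    p = ct$p.value,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = length(x)
  )
}

#' Cluster species into PM retention-capacity tiers
#'
#' K-means (Lloyd's algorithm via [stats::kmeans()], best of `n_restarts`
#' random starts by total within-cluster sum of squares) on standardized
#' per-species features.  Cluster labels are renumbered so that cluster 1
#' has the smallest mean total PM and cluster `k` the largest.
#'
#' @param features Tibble: `species_id`, numeric feature columns (the 8
#'   inventory-cell densities and a `total` column), one row per species.
#' @param k Number of clusters, default 3 (low / intermediate / high
#'   capacity).
#' @param seed Integer seed for the restarts.
#' @param n_restarts Number of random starts, default 50.
#' @param total_col Column used to order the clusters, default `"total"`;
#'   must be present.
#' @return List: `assignments` (tibble `species_id`, `cluster`), `centers`
#'   (matrix, standardized space, rows in renumbered order), `sizes`,
#'   `tot_withinss`.
#' @export
kmeans_capacity_clusters <- function(features, k = 3, seed = 20181218,
                                     n_restarts = 50, total_col = "total") {
  stopifnot("species_id" %in% names(features), total_col %in% names(features))
  num <- features |> dplyr::select(-"species_id")
  if (!all(vapply(num, is.numeric, logical(1)))) {
    ld_abort("all feature columns must be numeric", "leafdepo_validation_error")
  }
  if (nrow(features) < k) {
    ld_abort(sprintf("need at least k = %d species, got %d", k, nrow(features)),
             "leafdepo_validation_error")
  }
  x <- scale(as.matrix(num))
  # constant columns scale to NaN; they carry no information for clustering
  x[, apply(as.matrix(num), 2, stats::sd) == 0] <- 0
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  km <- withr_seed(stats::kmeans(x, centers = k, nstart = n_restarts,
                                 iter.max = 100, algorithm = "Lloyd"))
  # renumber: cluster 1 = lowest mean total PM, k = highest
  mean_total <- tapply(features[[total_col]], km$cluster, mean)
  ord <- order(mean_total)
  relabel <- integer(k)
  relabel[as.integer(names(mean_total)[ord])] <- seq_len(k)
  list(
    assignments = tibble::tibble(
      species_id = features$species_id,
      cluster = relabel[km$cluster]
    ),
    centers = km$centers[as.integer(names(mean_total)[ord]), , drop = FALSE],
    sizes = as.integer(km$size[as.integer(names(mean_total)[ord])]),
    tot_withinss = km$tot.withinss
  )
}
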