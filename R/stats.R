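#' Nested dataset
#'
#' Point measurements with a two-level nesting structure: scales within
#' individuals within treatment/color groups. The individual is the
#' exchangeable unit for permutation inference.
#'
#' @param value numeric measurements (e.g. corrected thickness, nm).
#' @param group fixed-effect factor (treatment or color group).
#' @param individual,scale nested random-effect identifiers; `scale` ids need
#'   only be unique within an individual.
#' @return object of class `nested_dataset` (a data.frame).
#' @export
nested_dataset <- function(value, group, individual, scale) {
  d <- data.frame(value = as.numeric(value), group = as.factor(group),
                  individual = as.factor(paste0(group, "/", individual)),
                  scale = as.factor(paste0(group, "/", individual, "/", scale)))
  if (any(!is.finite(d$value))) stop("values must be finite")
  if (nlevels(d$group) < 2) stop("need at least 2 groups")
  class(d) <- c("nested_dataset", "data.frame")
  d
}

# per-individual means and their group labels (the collapsed design on which
# permutation and post-hoc statistics operate)
individual_means <- function(data) {
  m <- tapply(data$value, data$individual, mean)
  g <- tapply(as.character(data$group), data$individual, function(x) x[1])
  data.frame(individual = names(m), group = factor(unname(g)),
             mean = unname(as.numeric(m)))
}

# one-way F statistic on a numeric vector by group; statistic of the
# permutation test (cheap enough for thousands of permutations)
oneway_F <- function(x, g) {
  n <- tapply(x, g, length); m <- tapply(x, g, mean)
  gm <- mean(x)
  ssb <- sum(n * (m - gm)^2); ssw <- sum((x - m[g])^2)
  k <- length(n); N <- length(x)
  if (ssw <= 0) return(if (ssb > 0) Inf else 0)
  (ssb / (k - 1)) / (ssw / (N - k))
}

#' Hierarchical (nested) group comparison by permutation
#'
#' Tests whether group means differ, accounting for non-independence of
#' repeated measures per scale and repeated scales per individual. Variance
#' components (individual, scale-within-individual, residual) are estimated
#' by REML on the two-level random-effects model; significance comes from a
#' permutation scheme that reassigns whole individuals to groups -- the
#' exchangeable unit -- preserving all within-individual structure. The
#' permutation statistic is the one-way F on per-individual means. Exact
#' reproduction of mixed-model Type III / Satterthwaite p-values is
#' deliberately not attempted.
#'
#' @param data a [nested_dataset()].
#' @param n_perm number of random permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @param varcomp `"reml"` (estimate components via lme4) or `"none"` (skip;
#'   useful in simulation loops).
#' @return list with `p_value`, `statistic` (observed F on individual
#'   means), `n_perm`, and `variance_components` (named: individual, scale,
#'   residual; `NULL` when skipped).
#' @export
nested_group_test <- function(data, n_perm = 9999, seed = 1,
                              varcomp = c("reml", "none")) {
  stopifnot(inherits(data, "nested_dataset"))
  varcomp <- match.arg(varcomp)
  im <- individual_means(data)
  per_group <- table(im$group)
  if (any(per_group < 2))
    stop("each group needs >= 2 individuals (fixed effect otherwise ",
         "confounded with the individual random effect)")
  F_obs <- oneway_F(im$mean, im$group)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  F_perm <- replicate(n_perm, oneway_F(im$mean, sample(im$group)))
  p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (1 + n_perm)
  vc <- NULL
  if (varcomp == "reml") {
    fit <- lme4::lmer(value ~ group + (1 | individual) + (1 | scale),
                      data = data, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    v <- as.data.frame(lme4::VarCorr(fit))
    vc <- c(individual = v$vcov[v$grp == "individual"],
            scale = v$vcov[v$grp == "scale"],
            residual = v$vcov[v$grp == "Residual"])
  }
  list(p_value = p, statistic = F_obs, n_perm = n_perm,
       variance_components = vc)
}

#' Pairwise post-hoc comparison of groups
#'
#' All pairwise group comparisons on per-individual means with pooled
#' within-group variance, with a studentized-range (Tukey HSD style)
#' family-wise adjustment. Adjusted p is monotone in -- and never smaller
#' than -- the raw pairwise p.
#'
#' @param data a [nested_dataset()] with at least 3 groups.
#' @return list with `pairs` (data.frame: group1, group2, diff, t, raw_p,
#'   adj_p) and `adjusted` (symmetric matrix of adjusted p-values).
#' @export
pairwise_posthoc <- function(data) {
  stopifnot(inherits(data, "nested_dataset"))
  im <- individual_means(data)
  k <- nlevels(im$group)
  if (k < 3) stop("post-hoc comparison needs >= 3 groups")
  if (any(table(im$group) < 2)) stop("each group needs >= 2 individuals")
  n <- tapply(im$mean, im$group, length)
  m <- tapply(im$mean, im$group, mean)
  df <- sum(n) - k
  s2 <- sum(tapply(im$mean, im$group, function(x) sum((x - mean(x))^2))) / df
  gl <- levels(im$group)
  pairs <- t(utils::combn(k, 2))
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    se <- sqrt(s2 * (1 / n[i] + 1 / n[j]))
    tt <- if (se > 0) (m[i] - m[j]) / se else if (m[i] == m[j]) 0 else Inf
    raw <- 2 * stats::pt(-abs(tt), df)
    adj <- stats::ptukey(sqrt(2) * abs(tt), k, df, lower.tail = FALSE)
    data.frame(group1 = gl[i], group2 = gl[j], diff = unname(m[i] - m[j]),
               t = unname(tt), raw_p = unname(raw),
               adj_p = unname(max(adj, raw)))
  }))
  adjm <- matrix(NA_real_, k, k, dimnames = list(gl, gl))
  for (r in seq_len(nrow(res))) {
    adjm[res$group1[r], res$group2[r]] <- res$adj_p[r]
    adjm[res$group2[r], res$group1[r]] <- res$adj_p[r]
  }
  diag(adjm) <- 1
  list(pairs = res, adjusted = adjm)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with an exact-enumeration branch for small samples
#' (n + m <= 12: the two-sided p is computed by enumerating all C(n+m, n)
#' assignments of the pooled values, ties handled via midranks) and a normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param x,y numeric samples.
#' @return list with `U` (statistic for `x`), `p_value` (two-sided), and
#'   `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty input")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  center <- n * m / 2
  if (N <= 12) {
    idx <- utils::combn(N, n)
    dev_obs <- abs(U_obs - center)
    U_all <- apply(idx, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
    p <- mean(abs(U_all - center) >= dev_obs - 1e-9)
    return(list(U = U_obs, p_value = p, method = "exact"))
  }
  ties <- table(pooled)
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U_obs, p_value = 1, method = "normal"))
  z <- (abs(U_obs - center) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(U = U_obs, p_value = p, method = "normal")
}

#' Natural-breaks grouping on two color metrics
#'
#' Groups specimens by cutting each metric (mean lamina thickness and
#' weighted average reflected wavelength) at its k-1 largest gaps between
#' sorted values. The two partitions are compared: when they coincide the
#' assignment is declared in agreement; otherwise both are returned with a
#' conflict flag. Group labels follow the thin-film color sequence in order
#' of increasing thickness.
#'
#' @param mean_thickness numeric vector, one value per specimen.
#' @param wav weighted average reflected wavelength per specimen (same
#'   length); pass `NULL` to group on thickness alone.
#' @param k number of groups (default 5).
#' @param labels group labels, thinnest first.
#' @return object of class `color_groups`: list with `assignment` (factor,
#'   thickness-based), `groups_thickness`, `groups_wav` (integer
#'   memberships), `breaks_thickness`, `breaks_wav` (cut points),
#'   `agreement` (logical).
#' @export
natural_breaks_grouping <- function(mean_thickness, wav = NULL, k = 5,
                                    labels = c("gold", "red", "indigo",
                                               "blue", "green")) {
  n <- length(mean_thickness)
  if (k > n) stop("k must not exceed the number of specimens")
  if (k < 1) stop("k must be >= 1")
  cut_one <- function(v) {
    o <- order(v)
    gaps <- diff(v[o])
    cuts <- sort(order(gaps, decreasing = TRUE)[seq_len(k - 1)])
    memb_sorted <- cumsum(c(1L, as.integer(seq_len(n - 1) %in% cuts)))
    memb <- integer(n); memb[o] <- memb_sorted
    list(membership = memb,
         breaks = if (k > 1) (v[o][cuts] + v[o][cuts + 1]) / 2 else numeric(0))
  }
  gt <- cut_one(mean_thickness)
  gw <- if (!is.null(wav)) {
    stopifnot(length(wav) == n)
    cut_one(wav)
  } else gt
  agreement <- identical(gt$membership, relabel_to(gw$membership, gt$membership))
  lab <- if (length(labels) >= k) labels[seq_len(k)] else as.character(seq_len(k))
  structure(list(assignment = factor(lab[gt$membership], levels = lab),
                 groups_thickness = gt$membership,
                 groups_wav = gw$membership,
                 breaks_thickness = gt$breaks,
                 breaks_wav = gw$breaks,
                 agreement = agreement),
            class = "color_groups")
}

# relabel partition b so its labels best align with partition a (labels are
# arbitrary; only the grouping matters for agreement)
relabel_to <- function(b, a) {
  map <- integer(max(b))
  for (g in unique(b)) {
    tab <- table(a[b == g])
    map[g] <- as.integer(names(tab)[which.max(tab)])
  }
  map[b]
}
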