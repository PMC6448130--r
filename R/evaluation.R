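#' Survival table
#'
#' @param sample_ids character identifiers.
#' @param time nonnegative follow-up times (days).
#' @param event event indicator: 1 = death observed, 0 = censored.
#' @return A list of class `survival_table`.
#' @export
survival_table <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  time <- as.numeric(time)
  event <- as.integer(event)
  stopifnot(length(sample_ids) == length(time),
            length(time) == length(event))
  if (any(time < 0)) stopf("survival times must be nonnegative")
  if (!all(event %in% c(0L, 1L))) stopf("event must be 0 (censored) or 1")
  structure(list(sample_ids = sample_ids, time = time, event = event),
            class = "survival_table")
}

#' Read a survival table from TSV (columns sample_id, time, event)
#' @param path file path.
#' @return A [survival_table()].
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "time", "event") %in% names(df)))
    stopf("%s: need columns sample_id, time, event", path)
  survival_table(df$sample_id, df$time, df$event)
}

# align two labelings on their shared sample universe; errors on mismatch
align_labels <- function(a, b) {
  la <- labels_of(a); lb <- labels_of(b)
  if (inherits(a, "cluster_assignment") && inherits(b, "cluster_assignment")) {
    if (!setequal(a$sample_ids, b$sample_ids))
      stopf("labelings cover different sample sets")
    lb <- lb[match(a$sample_ids, b$sample_ids)]
  } else if (length(la) != length(lb)) {
    stopf("labelings have different lengths (%d vs %d)",
          length(la), length(lb))
  }
  list(a = la, b = lb)
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information between two labelings
#'
#' Mutual information of the label contingency table (natural log),
#' normalized by default by the arithmetic mean of the two label entropies.
#' Two single-cluster labelings have NMI 1 by the 0/0 convention.
#'
#' @param a,b labelings: [cluster_assignment()] objects (matched by sample
#'   id) or plain integer vectors of equal length.
#' @param normalization `"arithmetic"` (default), `"max"`, or `"sqrt"` mean
#'   of the entropies as denominator.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b, normalization = c("arithmetic", "max", "sqrt")) {
  normalization <- match.arg(normalization)
  al <- align_labels(a, b)
  tab <- table(al$a, al$b)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  ha <- entropy_nat(px); hb <- entropy_nat(py)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  denom <- switch(normalization,
                  arithmetic = (ha + hb) / 2,
                  max = max(ha, hb),
                  sqrt = sqrt(ha * hb))
  if (denom == 0) return(1)      # both labelings single-cluster
  max(0, min(1, mi / denom))
}

# all permutations of 1..k (k <= 8)
permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in permutations_of(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Clustering accuracy under optimal label matching
#'
#' Cluster labels are arbitrary, so accuracy is computed under the label
#' permutation that maximizes agreement with the reference (exhaustive
#' search over the confusion matrix; label alphabets up to size 8).
#'
#' @param pred,truth labelings as in [nmi()].
#' @return Fraction of samples agreeing under the best matching.
#' @export
matched_accuracy <- function(pred, truth) {
  al <- align_labels(pred, truth)
  tab <- table(al$a, al$b)
  k <- max(dim(tab))
  if (k > 8L) stopf("optimal matching implemented for up to 8 labels (got %d)", k)
  M <- matrix(0, k, k)
  M[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  best <- max(vapply(permutations_of(k),
                     function(p) sum(M[cbind(seq_len(k), p)]), numeric(1)))
  best / length(al$a)
}

#' Chi-square association between two categorical labelings
#'
#' Pearson chi-square on the contingency table, no continuity correction;
#' all-zero rows/columns are dropped with a warning.
#'
#' @param a a labeling as in [nmi()].
#' @param b a categorical labeling (factor/character/integer vector, or
#'   `cluster_assignment`).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_association <- function(a, b) {
  if (inherits(a, "cluster_assignment") && inherits(b, "cluster_assignment")) {
    al <- align_labels(a, b)
    la <- factor(al$a); lb <- factor(al$b)
  } else {
    la <- if (is.factor(a)) a else factor(labels_of_any(a))
    lb <- if (is.factor(b)) b else factor(labels_of_any(b))
  }
  if (length(la) != length(lb)) stopf("labelings differ in length")
  tab <- table(la, lb)
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warnf("dropping %d empty row(s)/column(s) from the contingency table",
          sum(!keep_r) + sum(!keep_c))
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stopf("need at least 2 categories on each side")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

labels_of_any <- function(x) {
  if (inherits(x, "cluster_assignment")) x$labels
  else if (is.factor(x) || is.character(x)) as.integer(factor(x))
  else as.integer(x)
}

# join a grouping with a survival table by sample id
join_survival <- function(groups, surv) {
  stopifnot(inherits(surv, "survival_table"))
  g <- labels_of_any(groups)
  if (inherits(groups, "cluster_assignment")) {
    idx <- match(groups$sample_ids, surv$sample_ids)
    if (anyNA(idx))
      stopf("survival table missing %d sample(s) present in the grouping",
            sum(is.na(idx)))
    data.frame(time = surv$time[idx], event = surv$event[idx], group = g)
  } else {
    if (length(g) != length(surv$time))
      stopf("grouping and survival table differ in length")
    data.frame(time = surv$time, event = surv$event, group = g)
  }
}

#' K-sample log-rank test
#'
#' Compares survival distributions across groups: observed minus expected
#' events per group accumulated over pooled event times with hypergeometric
#' variance, chi-square distributed with k-1 degrees of freedom under the
#' null.
#'
#' @param groups a [cluster_assignment()] or integer vector of group labels.
#' @param surv a [survival_table()].
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(groups, surv) {
  df <- join_survival(groups, surv)
  df <- df[!is.na(df$group), , drop = FALSE]
  groups_present <- unique(df$group)
  if (length(groups_present) < 2L)
    stopf("log-rank test needs at least two non-empty groups")
  if (sum(df$event) == 0L)
    stopf("log-rank test needs at least one observed event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(fit$n)
  stat <- unname(fit$chisq)
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; censored subjects leave
#' the risk set without causing a drop. The returned step function starts at
#' `S(0) = 1`.
#'
#' @param surv a [survival_table()].
#' @return Data frame with columns `time` (including 0) and `surv`.
#' @export
kaplan_meier_curve <- function(surv) {
  stopifnot(inherits(surv, "survival_table"))
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ 1)
  data.frame(time = c(0, fit$time), surv = c(1, fit$surv))
}
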