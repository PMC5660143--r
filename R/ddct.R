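#' Per-sample delta-Ct with spike-in/housekeeper or rRNA normalization
#'
#' \code{"spike_housekeeper"} normalizes each assay target to the mean of
#' the spike-in and housekeeper channel Cts (arithmetic mean of Ct values,
#' i.e. geometric mean of linear abundances), the policy used for RNase R
#' validation assays. \code{"28S"} normalizes to the reference-rRNA
#' channel, the variant used for patient-sample comparisons. Samples
#' missing a required normalizer are excluded with a warning.
#'
#' @param ct_table data.frame(sample, group, target, role, replicate, ct)
#' @param policy \code{"spike_housekeeper"} or \code{"28S"}
#' @return data.frame(sample, group, target, delta_ct)
#' @export
delta_ct <- function(ct_table, policy = c("spike_housekeeper", "28S")) {
  policy <- match.arg(policy)
  rows <- list()
  for (smp in unique(ct_table$sample)) {
    st <- ct_table[ct_table$sample == smp, , drop = FALSE]
    norm <- if (policy == "spike_housekeeper") {
      sp <- st$ct[st$role == "spike_in"]
      hk <- st$ct[st$role == "housekeeper"]
      if (!length(sp) || !length(hk)) NA_real_ else
        mean(c(mean(sp), mean(hk)))
    } else {
      rr <- st$ct[st$role == "reference_rRNA"]
      if (!length(rr)) NA_real_ else mean(rr)
    }
    if (is.na(norm)) {
      warning(sprintf("sample %s lacks normalizer; excluded", smp))
      next
    }
    for (tg in unique(st$target[st$role == "assay"])) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, group = st$group[1], target = tg,
        delta_ct = mean(st$ct[st$target == tg]) - norm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sample = character(0), group = character(0),
                      target = character(0), delta_ct = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Delta-delta-Ct fold change
#'
#' fold = 2^-(delta_ct_case - delta_ct_control).
#'
#' @param delta_ct_case,delta_ct_control delta-Ct values (vectorized)
#' @return fold change
#' @export
ddct_fold <- function(delta_ct_case, delta_ct_control) {
  2^-(delta_ct_case - delta_ct_control)
}

#' Group comparison of expression values
#'
#' Mean and SEM per group, plus a two-sample two-sided t test with samples
#' and technical replicates pooled as individual observations. Classical
#' Student (equal-variance) by default; Welch behind the flag.
#'
#' @param values numeric observations
#' @param groups factor/character of length \code{values} with two levels
#' @param test \code{"student"} or \code{"welch"}
#' @return list(summary = per-group mean/sem/n, t, df, p)
#' @export
group_compare <- function(values, groups, test = c("student", "welch")) {
  test <- match.arg(test)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) .fail("need exactly two groups")
  if (any(table(groups) < 2L)) .fail("each group needs >= 2 observations")
  summ <- do.call(rbind, lapply(lv, function(g) {
    v <- values[groups == g]
    data.frame(group = g, mean = mean(v), sem = sd(v) / sqrt(length(v)),
               n = length(v), stringsAsFactors = FALSE)
  }))
  # degenerate zero-variance groups: identical -> t = 0, p = 1; perfectly
  # separated constants -> infinite t, p = 0
  if (sd(values[groups == lv[1]]) == 0 && sd(values[groups == lv[2]]) == 0) {
    same_mean <- mean(values[groups == lv[1]]) ==
      mean(values[groups == lv[2]])
    return(list(summary = summ, t = if (same_mean) 0 else Inf,
                df = length(values) - 2L, p = if (same_mean) 1 else 0))
  }
  ht <- t.test(values[groups == lv[1]], values[groups == lv[2]],
               var.equal = (test == "student"))
  list(summary = summ, t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}

#' Full delta-delta-Ct analysis of a Ct table
#'
#' Computes per-sample delta-Ct, per-sample fold change relative to the
#' mean control delta-Ct, and the case-vs-control group test on fold
#' values.
#'
#' @param ct_table Ct table (see \code{\link{delta_ct}})
#' @param control name of the control group
#' @param policy normalizer policy
#' @param test t-test flavor
#' @return list(per_sample, per_target = fold estimates and tests)
#' @export
ddct_analysis <- function(ct_table, control,
                          policy = c("spike_housekeeper", "28S"),
                          test = c("student", "welch")) {
  dct <- delta_ct(ct_table, policy)
  if (!control %in% dct$group) .fail("control group %s absent", control)
  per_target <- do.call(rbind, lapply(unique(dct$target), function(tg) {
    d <- dct[dct$target == tg, , drop = FALSE]
    ref <- mean(d$delta_ct[d$group == control])
    d$fold <- ddct_fold(d$delta_ct, ref)
    cases <- unique(d$group[d$group != control])
    do.call(rbind, lapply(cases, function(cg) {
      sub <- d[d$group %in% c(control, cg), ]
      gc <- group_compare(sub$fold, sub$group, test)
      data.frame(target = tg, case_group = cg,
                 fold = mean(d$fold[d$group == cg]),
                 t = gc$t, p = gc$p, stringsAsFactors = FALSE)
    }))
  }))
  dct$fold <- NA_real_
  for (tg in unique(dct$target)) {
    ref <- mean(dct$delta_ct[dct$target == tg & dct$group == control])
    dct$fold[dct$target == tg] <- ddct_fold(dct$delta_ct[dct$target == tg],
                                            ref)
  }
  list(per_sample = dct, per_target = per_target)
}
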