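# Independent brute-force oracles, computed straight from the raw evidence
# and phenotype data frames by scanning every (junction, sample) pair.

oracle_key <- function(ev) paste(ev$chrom, ev$start, ev$end, ev$strand)

# novelty stage per (cancer cohort, junction): plain loops, no store queries
oracle_stages <- function(evidence, phenotypes, match_map, min_total_reads = 2) {
  ev <- as.data.frame(evidence)
  ph <- as.data.frame(phenotypes)
  ev$key <- oracle_key(ev)
  totals <- tapply(ev$reads, ev$key, sum)
  keep <- names(totals)[totals >= min_total_reads]
  ev <- ev[ev$key %in% keep, ]
  class_of <- setNames(ph$cohort_class, ph$sample_id)
  cohort_of <- setNames(ph$cohort, ph$sample_id)
  core <- c("matched_normal", "gtex_normal")
  sra <- c("sra_adult", "sra_developmental", "sra_placenta", "sra_stem")
  out <- list()
  for (cc in sort(unique(ph$cohort[ph$cohort_class == "tumor"]))) {
    keys <- unique(ev$key[cohort_of[ev$sample_id] == cc])
    if (length(keys) == 0) next
    matched <- match_map[[cc]]
    for (k in sort(keys)) {
      rows <- ev[ev$key == k, ]
      in_core <- any(class_of[rows$sample_id] %in% core)
      in_sra <- any(class_of[rows$sample_id] %in% sra)
      in_tm <- length(matched) > 0 && any(cohort_of[rows$sample_id] %in% matched)
      stage <- if (!in_core && !in_sra) "3+"
      else if (!in_core) "2+"
      else if (length(matched) > 0 && !in_tm) "1+"
      else "0"
      out[[length(out) + 1]] <- data.frame(cohort = cc, key = k, stage = stage)
    }
  }
  do.call(rbind, out)
}

# set flags per (cohort, stage-2+ junction) under either rule
oracle_sets <- function(evidence, phenotypes, stages, rule = "default",
                        sra_cancer_map = NULL) {
  ev <- as.data.frame(evidence)
  ph <- as.data.frame(phenotypes)
  ev$key <- oracle_key(ev)
  class_of <- setNames(ph$cohort_class, ph$sample_id)
  cohort_of <- setNames(ph$cohort, ph$sample_id)
  s2 <- stages[stages$stage %in% c("2+", "3+"), ]
  if (is.null(s2) || nrow(s2) == 0) return(NULL)
  out <- list()
  for (i in seq_len(nrow(s2))) {
    k <- s2$key[i]
    rows <- ev[ev$key == k, ]
    smp <- unique(rows$sample_id)
    n_ad <- sum(class_of[smp] == "sra_adult")
    n_de <- sum(class_of[smp] == "sra_developmental")
    n_pl <- sum(class_of[smp] == "sra_placenta")
    n_st <- sum(class_of[smp] == "sra_stem")
    if (rule == "default") {
      fl <- c(adult = n_ad >= 1, dev = n_de >= 1, pla = n_pl >= 1, stem = n_st >= 1)
    } else {
      grp_dev <- n_de + n_pl
      fl <- c(adult = n_ad >= 2, dev = n_de >= 1 && grp_dev >= 2,
              pla = n_pl >= 1 && grp_dev >= 2, stem = n_st >= 2)
    }
    in_sc <- FALSE
    if (!is.null(sra_cancer_map) && s2$cohort[i] %in% names(sra_cancer_map)) {
      in_sc <- any(cohort_of[smp] == sra_cancer_map[[s2$cohort[i]]] &
                     class_of[smp] == "sra_cancer")
    }
    out[[length(out) + 1]] <- data.frame(
      cohort = s2$cohort[i], key = k,
      adult = unname(fl["adult"]), dev = unname(fl["dev"]),
      pla = unname(fl["pla"]), stem = unname(fl["stem"]),
      unexplained = !any(fl), in_sra_cancer = in_sc
    )
  }
  do.call(rbind, out)
}

# per-cohort prevalence by scanning the raw table
oracle_prevalence <- function(evidence, phenotypes, cohort) {
  ev <- as.data.frame(evidence)
  ph <- as.data.frame(phenotypes)
  ev$key <- oracle_key(ev)
  in_cohort <- ph$sample_id[ph$cohort == cohort]
  keys <- sort(unique(ev$key[ev$sample_id %in% in_cohort]))
  n_pos <- vapply(keys, function(k) {
    length(unique(ev$sample_id[ev$key == k & ev$sample_id %in% in_cohort]))
  }, integer(1))
  data.frame(key = keys, n_positive = unname(n_pos),
             prevalence = unname(n_pos) / length(in_cohort))
}

# Kruskal-Wallis H by the rank formula (no ties assumed)
oracle_kw_h <- function(a, b) {
  x <- c(a, b)
  r <- rank(x)
  n <- length(x)
  ra <- sum(r[seq_along(a)])
  rb <- sum(r[-seq_along(a)])
  12 / (n * (n + 1)) * (ra^2 / length(a) + rb^2 / length(b)) - 3 * (n + 1)
}

# exact permutation p-value for the two-group KW statistic
oracle_kw_perm_p <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(x), na)
  obs <- oracle_kw_h(a, b)
  stats <- apply(idx, 2, function(i) oracle_kw_h(x[i], x[-i]))
  mean(stats >= obs - 1e-12)
}

# two-sided Fisher p by hypergeometric enumeration over fixed margins
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b        # row 1
  n2 <- c_ + d      # row 2
  k <- a + c_       # col 1
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# product-limit estimate by hand
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}
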