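# Percent-identity analyses: pairwise protein identity, per-orthogroup
# within/donor PID summaries, the seventy-percent-rule audit, and the
# cumulative-effects suite (Kendall trend, Jonckheere-Terpstra,
# size-matched rank-sum comparisons).

#' Percent identity between two protein sequences
#'
#' Globally aligns the two sequences (Needleman-Wunsch, BLOSUM62, affine
#' gaps) and returns the percentage of identical residues over aligned
#' columns where both sequences have a residue (gap columns are excluded
#' from the denominator).
#'
#' @param seq_a,seq_b Protein sequences as character strings (or anything
#'   [Biostrings::AAString()] accepts).
#' @return Percent identity in \[0, 100\].
#' @examples
#' pairwise_pid("AAAA", "AAAT") # 75
#' @export
pairwise_pid <- function(seq_a, seq_b) {
  seq_a <- as.character(seq_a); seq_b <- as.character(seq_b)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  a <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) return(0)
  100 * sum(a[both] == b[both]) / sum(both)
}

pid_stats <- function(v) c(mean = mean(v), min = min(v), max = max(v))

#' Per-orthogroup percent-identity summary
#'
#' Within-PID is summarized over all focal-focal sequence pairs and
#' donor-PID over all focal-donor pairs (mean/min/max each). The maximum
#' focal-donor pair identity is tracked separately as `max_candidate_pid`,
#' the quantity audited by the seventy-percent rule (which applies per
#' candidate, not to the orthogroup average).
#'
#' @param sequences Named character vector of protein sequences for the
#'   orthogroup members.
#' @param focal_ids Names of the focal (Cyanidiales) members.
#' @param donor_ids Names of the non-eukaryotic members to compare against
#'   (the classifier's donor set for HGT orthogroups; all non-eukaryotes
#'   for native ones). May be empty: donor statistics are then missing.
#' @param og_id Orthogroup identifier.
#' @return List of class `og_pid_summary` with `og_id`, `pid_within`,
#'   `pid_to_donor` (or `NULL`), `max_candidate_pid`, `n_focal`, `n_donor`.
#' @export
og_pid_summary <- function(sequences, focal_ids, donor_ids = character(),
                           og_id = "OG") {
  if (!length(focal_ids)) stop("orthogroup needs at least one focal member")
  miss <- setdiff(c(focal_ids, donor_ids), names(sequences))
  if (length(miss)) stop("sequence(s) missing: ", paste(miss, collapse = ", "))
  within <- if (length(focal_ids) >= 2) {
    pairs <- utils::combn(focal_ids, 2)
    apply(pairs, 2, function(p) pairwise_pid(sequences[[p[1]]], sequences[[p[2]]]))
  } else {
    100
  }
  donor <- NULL
  max_cand <- NA_real_
  if (length(donor_ids)) {
    fd <- expand.grid(f = focal_ids, d = donor_ids, stringsAsFactors = FALSE)
    pid_fd <- mapply(function(f, d) pairwise_pid(sequences[[f]], sequences[[d]]),
                     fd$f, fd$d)
    donor <- pid_stats(pid_fd)
    max_cand <- max(pid_fd)
  }
  structure(
    list(og_id = og_id, pid_within = pid_stats(within), pid_to_donor = donor,
         max_candidate_pid = max_cand,
         n_focal = length(focal_ids), n_donor = length(donor_ids)),
    class = "og_pid_summary"
  )
}

#' Audit the seventy-percent rule over orthogroup summaries
#'
#' The rule holds that eukaryotic genes sharing more than `threshold`
#' percent identity with prokaryotic homologs are assembly or annotation
#' artifacts; here it is audited, not assumed. Orthogroups are partitioned
#' by whether any individual candidate exceeds the threshold (strictly),
#' split by class, and exceedances are flagged as potentially
#' EGT-attributable when a donor phylum is Cyanobacteria, Chlamydiae or
#' Proteobacteria.
#'
#' @param summaries `data.frame` with columns `og_id`, `class` (`"hgt"` or
#'   `"native"`), `max_candidate_pid`, and optionally `donor_phyla`
#'   (semicolon-separated).
#' @param threshold Percent-identity threshold (default 70; exceedance is
#'   strict `>`).
#' @return List of class `seventy_rule_audit` with counts, the percentage
#'   of HGT orthogroups over the threshold, and the flagged per-OG table.
#' @export
seventy_rule_audit <- function(summaries, threshold = 70) {
  s <- summaries
  over <- !is.na(s$max_candidate_pid) & s$max_candidate_pid > threshold
  egt_phyla <- c("Cyanobacteria", "Chlamydiae", "Proteobacteria")
  egt_attr <- rep(FALSE, nrow(s))
  if ("donor_phyla" %in% names(s)) {
    egt_attr <- vapply(strsplit(ifelse(is.na(s$donor_phyla), "", s$donor_phyla),
                                ";", fixed = TRUE),
                       function(p) any(p %in% egt_phyla), logical(1))
  }
  flagged <- s[over, , drop = FALSE]
  flagged$egt_attributable <- egt_attr[over]
  n_hgt <- sum(s$class == "hgt")
  n_hgt_over <- sum(over & s$class == "hgt")
  structure(
    list(threshold = threshold,
         n_total = nrow(s),
         n_hgt = n_hgt,
         n_hgt_over = n_hgt_over,
         percent_hgt_over = if (n_hgt) 100 * n_hgt_over / n_hgt else NA_real_,
         n_native_over = sum(over & s$class == "native"),
         n_under = sum(!over),
         n_over_egt_attributable = sum(egt_attr[over]),
         flagged = flagged),
    class = "seventy_rule_audit"
  )
}

#' @export
print.seventy_rule_audit <- function(x, ...) {
  cat(sprintf("Seventy-percent-rule audit (threshold %g%%):\n", x$threshold))
  cat(sprintf("  %d/%d HGT orthogroups over threshold (%.1f%%); %d native over; %d under\n",
              x$n_hgt_over, x$n_hgt, x$percent_hgt_over, x$n_native_over,
              x$n_under))
  invisible(x)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

kendall_s <- function(x, y) {
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  sum((sx * sy)[upper.tri(sx)])
}

#' Kendall rank-correlation trend between within-PID and donor-PID
#'
#' Tau-b with tie correction. The two-sided p-value is exact (full
#' enumeration of permutations) for n <= 8 and a tie-corrected normal
#' approximation above.
#'
#' @param x,y Paired numeric vectors (e.g. per-orthogroup within-PID and
#'   donor-PID), length >= 3.
#' @return A `stat_result` with `statistic` = tau-b.
#' @export
kendall_trend <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must be paired with length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("tau is undefined for a constant vector")
  }
  tau <- stats::cor(x, y, method = "kendall")
  n <- length(x)
  if (n <= 8) {
    s_obs <- kendall_s(x, y)
    perms <- all_perms(n)
    s_perm <- apply(perms, 1, function(p) kendall_s(x, y[p]))
    p <- mean(abs(s_perm) >= abs(s_obs) - 1e-9)
    method <- "Kendall tau-b (exact permutation)"
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                           exact = FALSE))
    p <- ct$p.value
    method <- "Kendall tau-b (normal approximation)"
  }
  stat_result(method, tau, p, n, n, tau)
}

#' Jonckheere-Terpstra statistic over ordered groups
#'
#' @param groups List of numeric vectors in their hypothesized order.
#' @return The JT statistic: over all ordered group pairs i < j, the count
#'   of cross-pairs with `x_i < x_j` plus half the ties.
#' @export
jt_statistic <- function(groups) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      cmp <- outer(groups[[i]], groups[[j]], "-")
      s <- s + sum(cmp < 0) + 0.5 * sum(cmp == 0)
    }
  }
  s
}

# enumerate all assignments of pooled indices to groups of given sizes;
# returns the JT statistic of every arrangement
jt_enumerate <- function(pool, sizes) {
  if (length(sizes) == 1) {
    return(jt_statistic(list(pool)))
  }
  first <- utils::combn(seq_along(pool), sizes[1], simplify = FALSE)
  unlist(lapply(first, function(idx) {
    g1 <- pool[idx]
    rest <- pool[-idx]
    sub <- jt_enumerate(rest, sizes[-1])
    # cross-pair contribution of group 1 against everything downstream
    cmp <- outer(g1, rest, "-")
    sub + sum(cmp < 0) + 0.5 * sum(cmp == 0)
  }))
}

n_arrangements <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' Tests for a monotone location trend over ordered groups (here:
#' donor-PID across orthogroup-size classes). The null distribution is
#' obtained by exact enumeration of all group-label arrangements when
#' there are at most `max_exact` of them, and by seedable random
#' permutation otherwise. The two-sided p-value is reported in
#' `$extra$p_two_sided`.
#'
#' @param groups List (>= 3) of non-empty numeric vectors in hypothesized
#'   order.
#' @param direction `"increasing"` (values rise along the order),
#'   `"decreasing"`, or `"two.sided"`.
#' @param n_perm Number of random permutations when enumeration is
#'   infeasible.
#' @param seed Optional integer seed.
#' @param max_exact Arrangement-count ceiling for exact enumeration.
#' @return A `stat_result` with `statistic` = JT.
#' @export
jonckheere_terpstra <- function(groups,
                                direction = c("increasing", "decreasing",
                                              "two.sided"),
                                n_perm = 1000, seed = NULL,
                                max_exact = 1e5) {
  direction <- match.arg(direction)
  if (length(groups) < 3) stop("need at least 3 ordered groups")
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("all groups must be non-empty")
  }
  sizes <- vapply(groups, length, integer(1))
  obs <- jt_statistic(groups)
  total_pairs <- (sum(sizes)^2 - sum(sizes^2)) / 2
  mu <- total_pairs / 2
  if (n_arrangements(sizes) <= max_exact) {
    null_jt <- jt_enumerate(unlist(groups), sizes)
    method <- "Jonckheere-Terpstra (exact enumeration)"
  } else {
    if (!is.null(seed)) set.seed(seed)
    pooled <- unlist(groups)
    null_jt <- vapply(seq_len(n_perm), function(i) {
      shuffled <- sample(pooled)
      jt_statistic(split_by_sizes(shuffled, sizes))
    }, numeric(1))
    method <- "Jonckheere-Terpstra (permutation)"
  }
  eps <- 1e-9
  n_null <- length(null_jt)
  mc <- !startsWith(method, "Jonckheere-Terpstra (exact")
  adj <- function(count) if (mc) (1 + count) / (n_null + 1) else count / n_null
  p_inc <- adj(sum(null_jt >= obs - eps))
  p_dec <- adj(sum(null_jt <= obs + eps))
  p_two <- adj(sum(abs(null_jt - mu) >= abs(obs - mu) - eps))
  p <- switch(direction, increasing = p_inc, decreasing = p_dec,
              two.sided = p_two)
  stat_result(method, obs, min(1, p), sizes[1], sum(sizes[-1]), obs - mu,
              extra = list(direction = direction, null_mean = mu,
                           p_two_sided = min(1, p_two), sizes = sizes))
}

# an all-tied rank-sum comparison has no evidence either way
finite_p <- function(p) if (is.finite(p)) p else 1

split_by_sizes <- function(x, sizes) {
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  lapply(seq_along(sizes), function(i) x[starts[i]:ends[i]])
}

#' Cumulative-effects test suite over orthogroup PID summaries
#'
#' Runs, on a table of per-orthogroup donor-PID summaries: (a) the global
#' HGT-vs-native rank-sum comparison of donor-PID; (b) a
#' Jonckheere-Terpstra trend of donor-PID over orthogroup size within each
#' class (direction: donor-PID decreasing with size, the erosion
#' expectation); (c) size-matched HGT-vs-native rank-sum tests with
#' Benjamini-Hochberg adjustment; (d) the three-way comparison of
#' shared-ancient vs Galdieria-exclusive vs Cyanidioschyzon-exclusive
#' donor-PID (pairwise rank-sum, BH). Tests whose inputs are degenerate
#' are skipped with a warning.
#'
#' @param summaries `data.frame` with columns `og_id`, `class` (`"hgt"` /
#'   `"native"`), `og_size` (number of Galdieria strains in the OG),
#'   `donor_pid` (mean percent identity to non-eukaryotes), and for HGT
#'   rows a `category` (`"shared"`, `"galdieria_only"`,
#'   `"cyanidioschyzon_only"`, ...).
#' @param n_perm Permutations for the trend tests.
#' @param seed Optional seed.
#' @return List of class `cumulative_effects` with elements
#'   `global` (stat_result), `trend_hgt`, `trend_native` (stat_results or
#'   `NULL`), `by_size` (`data.frame`), `by_category` (`data.frame`).
#' @export
cumulative_effects_suite <- function(summaries, n_perm = 1000, seed = NULL) {
  s <- summaries
  hgt <- s[s$class == "hgt", , drop = FALSE]
  nat <- s[s$class == "native", , drop = FALSE]
  out <- list(global = NULL, trend_hgt = NULL, trend_native = NULL,
              by_size = NULL, by_category = NULL)
  if (!nrow(hgt) || !nrow(nat)) {
    warning("one class empty; global and size-matched comparisons skipped")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(hgt$donor_pid, nat$donor_pid))
    out$global <- stat_result("Wilcoxon rank-sum (donor PID, HGT vs native)",
                              wt$statistic, finite_p(wt$p.value),
                              nrow(hgt), nrow(nat),
                              mean(hgt$donor_pid) - mean(nat$donor_pid))
  }
  trend_of <- function(d) {
    grp <- split(d$donor_pid, d$og_size)
    grp <- grp[vapply(grp, length, integer(1)) > 0]
    if (length(grp) < 3) {
      warning("fewer than 3 orthogroup-size groups; trend test skipped")
      return(NULL)
    }
    jonckheere_terpstra(grp, direction = "decreasing", n_perm = n_perm,
                        seed = seed)
  }
  if (nrow(hgt)) out$trend_hgt <- trend_of(hgt)
  if (nrow(nat)) out$trend_native <- trend_of(nat)
  if (nrow(hgt) && nrow(nat)) {
    sizes <- sort(intersect(unique(hgt$og_size), unique(nat$og_size)))
    rows <- lapply(sizes, function(sz) {
      a <- hgt$donor_pid[hgt$og_size == sz]
      b <- nat$donor_pid[nat$og_size == sz]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      data.frame(og_size = sz, n_hgt = length(a), n_native = length(b),
                 effect = mean(a) - mean(b), p_value = finite_p(wt$p.value))
    })
    by_size <- do.call(rbind, rows)
    if (!is.null(by_size) && nrow(by_size)) {
      by_size$p_adjusted <- benjamini_hochberg(by_size$p_value)
      out$by_size <- by_size
    }
  }
  if ("category" %in% names(hgt)) {
    cats <- c("shared", "galdieria_only", "cyanidioschyzon_only")
    have <- cats[cats %in% hgt$category]
    if (length(have) >= 2) {
      cmb <- utils::combn(have, 2, simplify = FALSE)
      rows <- lapply(cmb, function(pr) {
        a <- hgt$donor_pid[hgt$category == pr[1]]
        b <- hgt$donor_pid[hgt$category == pr[2]]
        if (length(a) < 2 || length(b) < 2) return(NULL)
        wt <- suppressWarnings(stats::wilcox.test(a, b))
        data.frame(group1 = pr[1], group2 = pr[2], n1 = length(a),
                   n2 = length(b), effect = mean(a) - mean(b),
                   p_value = finite_p(wt$p.value), stringsAsFactors = FALSE)
      })
      by_cat <- do.call(rbind, rows)
      if (!is.null(by_cat) && nrow(by_cat)) {
        by_cat$p_adjusted <- benjamini_hochberg(by_cat$p_value)
        out$by_category <- by_cat
      }
    }
  }
  structure(out, class = "cumulative_effects")
}

#' @export
print.cumulative_effects <- function(x, ...) {
  cat("Cumulative-effects suite\n")
  if (!is.null(x$global)) {
    cat(sprintf("  global donor-PID shift: %+.2f%%, p = %.3g\n",
                x$global$effect, x$global$p_value))
  }
  for (nm in c("trend_hgt", "trend_native")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %s: JT = %.1f, p = %.3g\n", nm, x[[nm]]$statistic,
                  x[[nm]]$p_value))
    }
  }
  invisible(x)
}
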