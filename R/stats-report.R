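#' One-way ANOVA on group data
#'
#' Standard fixed-effects decomposition: between-group sum of squares
#' `SS_b = sum n_g (mean_g - grand_mean)^2`, within-group
#' `SS_w = sum (y - mean_g)^2`, `F = MS_b / MS_w` on `(k - 1, N - k)`
#' degrees of freedom. The fit is delegated to [stats::aov()]. Degenerate
#' inputs are resolved explicitly: identical group means give `F = 0,
#' p = 1`; zero within-group variance with unequal means gives `F = Inf,
#' p = 0`, flagged.
#'
#' @param values numeric replicate values.
#' @param groups group label per value (>= 2 groups).
#' @return data.frame of class `anova_table` with rows between/within:
#'   `term`, `df`, `ss`, `ms`, `f`, `p`; attributes `means`, `n` (named
#'   per group), `df_within`, `ms_within`, `flag_zero_variance`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2) stop("one_way_anova: need at least 2 groups")
  if (any(!is.finite(values))) stop("one_way_anova: values must be finite")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]; df <- tab[["Df"]]
  ms <- ss / df
  flag <- FALSE
  if (ms[2] <= .Machine$double.eps * max(ss[1], 1)) {
    if (ms[1] <= .Machine$double.eps * max(abs(values), 1)) {
      f <- 0; p <- 1               # all observations identical
    } else {
      f <- Inf; p <- 0; flag <- TRUE  # separated means, no within scatter
    }
  } else {
    f <- ms[1] / ms[2]
    p <- stats::pf(f, df[1], df[2], lower.tail = FALSE)
  }
  out <- data.frame(term = c("between", "within"), df = df, ss = ss,
                    ms = ms, f = c(f, NA), p = c(p, NA),
                    stringsAsFactors = FALSE)
  attr(out, "means") <- tapply(values, groups, mean)
  attr(out, "n") <- as.vector(table(groups))
  names(attr(out, "n")) <- levels(groups)
  attr(out, "df_within") <- df[2]
  attr(out, "ms_within") <- ms[2]
  attr(out, "flag_zero_variance") <- flag
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Newman-Keuls step-down post-hoc pairwise comparisons
#'
#' Orders the group means and tests pairwise differences with the
#' studentized range: a pair whose ordered ranks straddle `p` means is
#' tested with `q = |mean_i - mean_j| / sqrt(MS_within / n_h)` (with `n_h`
#' the harmonic mean of the two group sizes) against the studentized-range
#' quantile at span `p` and the within degrees of freedom. Testing steps
#' down from the widest span inward, and every sub-range of a
#' non-significant range is declared non-significant without testing, so
#' the significant-pair set is closed under the range rule. Ties in the
#' ordered means are broken by group-label order.
#'
#' @param values,groups as in [one_way_anova()].
#' @param alpha family significance level (default 0.05).
#' @param anova optionally, the [one_way_anova()] table already computed on
#'   the same data.
#' @return data.frame of class `posthoc_result`, one row per pair:
#'   `group1`, `group2` (group1 has the smaller mean), `diff`
#'   (mean2 - mean1), `span`, `q`, `q_crit`, `tested`, `significant`;
#'   the ANOVA table in attribute `anova`.
#' @export
newman_keuls <- function(values, groups, alpha = 0.05, anova = NULL) {
  groups <- factor(groups)
  n_by_g <- table(groups)
  small <- names(n_by_g)[n_by_g < 2]
  if (length(small)) {
    warning("newman_keuls: excluding group(s) with n < 2: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("newman_keuls: fewer than 2 usable groups")
  if (is.null(anova)) anova <- one_way_anova(values, groups)
  means <- attr(anova, "means")
  ns <- attr(anova, "n")
  df_w <- attr(anova, "df_within")
  ms_w <- attr(anova, "ms_within")
  # ascending means; ties broken lexicographically by group label
  ord <- order(means, names(means))
  means <- means[ord]; ns <- ns[ord]
  k <- length(means)
  nonsig_ranges <- list()  # accepted (non-significant) index ranges
  rows <- list()
  for (span in k:2) {
    for (lo in seq_len(k - span + 1)) {
      hi <- lo + span - 1
      covered <- any(vapply(nonsig_ranges, function(rg) {
        lo >= rg[1] && hi <= rg[2]
      }, logical(1)))
      diff <- means[hi] - means[lo]
      n_h <- 2 / (1 / ns[lo] + 1 / ns[hi])
      q <- if (ms_w > 0) diff / sqrt(ms_w / n_h) else
        (if (diff > 0) Inf else 0)
      q_crit <- stats::qtukey(1 - alpha, span, df_w)
      if (covered) {
        sig <- FALSE; tested <- FALSE
      } else {
        tested <- TRUE
        sig <- q > q_crit
        if (!sig) nonsig_ranges[[length(nonsig_ranges) + 1]] <- c(lo, hi)
      }
      rows[[length(rows) + 1]] <- data.frame(
        group1 = names(means)[lo], group2 = names(means)[hi],
        diff = diff, span = span, q = q, q_crit = q_crit,
        tested = tested, significant = sig, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "anova") <- anova
  attr(out, "alpha") <- alpha
  class(out) <- c("posthoc_result", "data.frame")
  out
}

#' ANOVA + Newman-Keuls in one call on a long table
#'
#' @param data data.frame with `group` and `value` columns.
#' @param alpha family significance level.
#' @return list with `anova` and `posthoc`.
#' @export
anova_nk <- function(data, alpha = 0.05) {
  stopifnot(all(c("group", "value") %in% names(data)))
  an <- one_way_anova(data$value, data$group)
  list(anova = an,
       posthoc = newman_keuls(data$value, data$group, alpha, anova = an))
}

#' Assemble stage outputs into a report bundle
#'
#' Merges the group-summary tables of the pipeline stages into one long
#' CSV, writes every statistic plus the configuration snapshot (constants,
#' thresholds, seeds) as JSON, and a plain-text summary. All stages must
#' summarize the same experimental groups; mismatched label sets are an
#' error listing the offending labels. Output is deterministic: rerunning
#' with identical inputs reproduces the JSON byte for byte (no
#' timestamps).
#'
#' @param stages named list; each element a list with `summary` (data.frame
#'   with a `group` column) and optionally `stats` (an [anova_nk()] result)
#'   and extra fields kept in the JSON.
#' @param out_dir output directory (created if absent).
#' @param config configuration snapshot to embed (list).
#' @return invisible list of written paths.
#' @export
assemble_report <- function(stages, out_dir, config = list()) {
  if (!length(stages)) stop("assemble_report: no stage outputs")
  if (is.null(names(stages)) || any(!nzchar(names(stages)))) {
    stop("assemble_report: stages must be named")
  }
  group_sets <- lapply(stages, function(s) sort(unique(s$summary$group)))
  all_groups <- sort(unique(unlist(group_sets)))
  bad <- Filter(length, lapply(group_sets, function(g) setdiff(all_groups, g)))
  if (length(bad)) {
    stop("assemble_report: group labels differ across stages: ",
         paste(vapply(names(bad), function(nm) {
           paste0(nm, " missing {", paste(bad[[nm]], collapse = ","), "}")
         }, character(1)), collapse = "; "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(names(stages), function(nm) {
    s <- stages[[nm]]$summary
    metrics <- setdiff(names(s)[vapply(s, is.numeric, TRUE)], "group")
    do.call(rbind, lapply(metrics, function(m) {
      data.frame(stage = nm, group = s$group, metric = m, value = s[[m]],
                 stringsAsFactors = FALSE)
    }))
  }))
  csv_path <- file.path(out_dir, "group_summaries.csv")
  utils::write.csv(long, csv_path, row.names = FALSE)

  json_obj <- list(
    config = config,
    stages = lapply(stages, function(s) {
      out <- list(summary = s$summary)
      if (!is.null(s$stats)) {
        out$anova <- as.data.frame(s$stats$anova)
        out$posthoc <- as.data.frame(s$stats$posthoc)
      }
      extra <- setdiff(names(s), c("summary", "stats"))
      out[extra] <- s[extra]
      out
    })
  )
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(json_obj, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

  txt_path <- file.path(out_dir, "summary.txt")
  lines <- c("mitoquant report", "================", "")
  for (nm in names(stages)) {
    lines <- c(lines, paste0("[", nm, "]"))
    s <- stages[[nm]]$summary
    lines <- c(lines, utils::capture.output(print(s, row.names = FALSE)))
    if (!is.null(stages[[nm]]$stats)) {
      an <- stages[[nm]]$stats$anova
      lines <- c(lines, sprintf("  ANOVA F(%d, %d) = %.4g, p = %.4g",
                                an$df[1], an$df[2], an$f[1], an$p[1]))
      ph <- stages[[nm]]$stats$posthoc
      sig <- ph[ph$significant, , drop = FALSE]
      lines <- c(lines, if (nrow(sig)) {
        sprintf("  NK significant: %s vs %s (q = %.3g > %.3g)",
                sig$group1, sig$group2, sig$q, sig$q_crit)
      } else "  NK: no significant pairs")
    }
    lines <- c(lines, "")
  }
  writeLines(lines, txt_path)
  invisible(list(csv = csv_path, json = json_path, txt = txt_path))
}
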