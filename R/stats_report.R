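#' Summarize a replicate set
#'
#' Arithmetic mean and sample standard deviation (divisor n-1) of one
#' sample's replicate measurements. With a single value the sd is `NA`.
#'
#' @param values Numeric replicate measurements in one unit.
#' @return Named list `mean`, `sd`, `n`.
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no replicate values", call. = FALSE)
  list(
    mean = mean(values),
    sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
    n = length(values)
  )
}

check_groups <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- lengths(lapply(groups, stats::na.omit))
  if (any(sizes < 2L)) {
    stop("every group needs at least two values", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups
}

groups_to_df <- function(groups) {
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
}

#' One-way analysis of variance across sample groups
#'
#' Classical equal-variance one-way ANOVA of replicate measurements
#' across samples, delegating to `stats::oneway.test(var.equal = TRUE)`.
#' With two groups the F statistic equals the squared pooled-variance
#' two-sample t statistic.
#'
#' @param groups Named list of numeric vectors, one per sample; each with
#'   at least two values.
#' @return List with `f_statistic`, `p_value`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  groups <- check_groups(groups)
  df <- groups_to_df(groups)
  ft <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
  list(
    f_statistic = unname(ft$statistic),
    p_value = unname(ft$p.value),
    df_between = unname(ft$parameter[1L]),
    df_within = unname(ft$parameter[2L])
  )
}

#' Pairwise significance between sample groups
#'
#' Tests every unordered pair of groups. `method = "tukey"` (default)
#' uses Tukey's honest significant difference on the one-way ANOVA fit;
#' `method = "t"` uses unadjusted pooled-variance pairwise t tests.
#' Significance is declared at `p < alpha`.
#'
#' @inheritParams anova_oneway
#' @param alpha Significance level (default 0.05).
#' @param method `"tukey"` or `"t"`.
#' @return Data.frame with `group_a`, `group_b`, `p_value`, `significant`.
#' @export
pairwise_compare <- function(groups, alpha = 0.05, method = c("tukey", "t")) {
  method <- match.arg(method)
  groups <- check_groups(groups)
  df <- groups_to_df(groups)
  nms <- names(groups)
  pairs <- utils::combn(nms, 2L)
  if (method == "tukey") {
    tk <- stats::TukeyHSD(stats::aov(value ~ group, data = df))$group
    key <- paste(pairs[2L, ], pairs[1L, ], sep = "-")
    p <- tk[key, "p adj"]
  } else {
    pt <- stats::pairwise.t.test(df$value, df$group,
      p.adjust.method = "none", pool.sd = FALSE, var.equal = TRUE
    )$p.value
    p <- vapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]
      b <- pairs[2L, j]
      if (b %in% rownames(pt) && a %in% colnames(pt) && !is.na(pt[b, a])) {
        pt[b, a]
      } else {
        pt[a, b]
      }
    }, numeric(1L))
  }
  data.frame(
    group_a = pairs[1L, ], group_b = pairs[2L, ],
    p_value = unname(p), significant = unname(p) < alpha
  )
}

#' Assemble a nutrition report block
#'
#' Builds one method block of a nutrition table: per sample and analyte,
#' `mean +/- sd` with a significance mark for samples that differ
#' significantly from every other sample in at least one pairwise
#' comparison set. `NA` means (analyte not detected) are printed as
#' `"nd"` and excluded from marks.
#'
#' @param summaries Data.frame with columns `sample_id`, `analyte`,
#'   `mean`, `sd` (sd may be `NA`).
#' @param comparisons Optional data.frame as returned by
#'   [pairwise_compare()] with an additional `analyte` column; used to
#'   place significance marks on samples significantly different from all
#'   others for that analyte.
#' @param unit_note Footnote string describing units.
#' @return A `nutrition_report`: data.frame in wide form (analytes in
#'   rows, samples in columns, formatted `mean±sd` strings) with the raw
#'   summaries in attribute `"summaries"`.
#' @export
build_report <- function(summaries, comparisons = NULL, unit_note = "") {
  need <- c("sample_id", "analyte", "mean")
  if (!all(need %in% names(summaries))) {
    stop("summaries must have sample_id, analyte, mean columns", call. = FALSE)
  }
  if (!is.null(comparisons) && nrow(comparisons) > 0L) {
    orphans <- setdiff(
      unique(c(comparisons$group_a, comparisons$group_b)),
      unique(summaries$sample_id)
    )
    if (length(orphans) > 0L) {
      stop(sprintf(
        "comparison groups not present in summaries: %s",
        paste(orphans, collapse = ", ")
      ), call. = FALSE)
    }
  }
  samples <- unique(summaries$sample_id)
  analytes <- unique(summaries$analyte)
  starred <- function(analyte, sample) {
    if (is.null(comparisons) || nrow(comparisons) == 0L) {
      return(FALSE)
    }
    cmp <- comparisons[comparisons$analyte == analyte &
      (comparisons$group_a == sample | comparisons$group_b == sample), ,
    drop = FALSE
    ]
    nrow(cmp) > 0L && all(cmp$significant)
  }
  cell <- function(analyte, sample) {
    row <- summaries[summaries$analyte == analyte &
      summaries$sample_id == sample, , drop = FALSE]
    if (nrow(row) == 0L || is.na(row$mean[1L])) {
      return("nd")
    }
    mark <- if (starred(analyte, sample)) "*" else ""
    sd <- if ("sd" %in% names(row) && !is.na(row$sd[1L])) {
      sprintf(" ±%.3f", row$sd[1L])
    } else {
      ""
    }
    sprintf("%.3f%s%s", row$mean[1L], mark, sd)
  }
  wide <- data.frame(analyte = analytes)
  for (s in samples) {
    wide[[s]] <- vapply(analytes, cell, character(1L), sample = s)
  }
  attr(wide, "summaries") <- summaries
  attr(wide, "unit_note") <- unit_note
  class(wide) <- c("nutrition_report", "data.frame")
  wide
}

#' @export
print.nutrition_report <- function(x, ...) {
  df <- x
  class(df) <- "data.frame"
  attr(df, "summaries") <- NULL
  print(df, row.names = FALSE)
  note <- attr(x, "unit_note")
  if (nzchar(note)) cat(note, "\n")
  invisible(x)
}
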