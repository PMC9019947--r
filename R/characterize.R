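#' Format a count with its percentage of a denominator
#'
#' Renders `"count (pct%)"` with the percentage rounded to two decimals and
#' trailing zeros dropped (so 92.31, 63.9, and 0 render as printed in
#' clinical univariate tables). `big_mark` adds thousands separators to the
#' count (as in cohort summary tables).
#'
#' @param count non-negative integer numerator.
#' @param denom positive denominator.
#' @param big_mark thousands separator for the count (`""` for none).
#' @return character scalar, e.g. `"4300 (92.31%)"`.
#' @export
format_count_pct <- function(count, denom, big_mark = "") {
  if (denom <= 0) stop("'denom' must be positive", call. = FALSE)
  pct <- round(100 * count / denom, 2L)
  sprintf("%s (%s%%)",
          formatC(count, format = "d", big.mark = big_mark),
          format(pct, scientific = FALSE, trim = TRUE))
}

#' Display a p-value the way clinical tables print it
#'
#' Values below 1e-4 render as `"< .0001"`; otherwise the value is rounded
#' to four decimals.
#'
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 1e-4, "< .0001",
         format(round(p, 4L), scientific = FALSE, trim = TRUE))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson's statistic without continuity correction on
#' `rbind(c(a, b), c(c, d))`, with the p-value from the chi-square
#' distribution with 1 degree of freedom. The statistic is invariant to
#' swapping rows or swapping columns.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param correct apply Yates continuity correction (off by default, the
#'   large-sample convention).
#' @return list with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  tab <- rbind(c(a, b), c(c, d))
  if (any(tab < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: a row or column margin is zero", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Assign CC / non-CC roles to clusters
#'
#' A cluster whose CC fraction exceeds 0.5 and reaches `purity_floor` is a
#' CC cluster; a cluster whose non-CC fraction reaches `purity_floor` is the
#' non-CC reference; anything else is left unlabeled. CC clusters are
#' ordered by decreasing size and named `CC-1`, `CC-2`, ...; non-CC clusters
#' are named `non-CC` (suffixed by size rank if several qualify).
#'
#' @param labels cluster labels.
#' @param classes binary class per sample.
#' @param positive value of `classes` counted as CC (default `TRUE` for
#'   logical, `"CC"` otherwise).
#' @param purity_floor minimum dominant-class fraction to receive a role.
#' @return data.frame with one row per cluster: `cluster`, `size`,
#'   `cc_count`, `cc_fraction`, `role` (`"CC"`, `"non-CC"`, `"unlabeled"`),
#'   `name`.
#' @export
label_cluster_roles <- function(labels, classes, positive = NULL,
                                purity_floor = 0.7) {
  if (length(labels) != length(classes)) stop("length mismatch", call. = FALSE)
  positive <- positive %||% if (is.logical(classes)) TRUE else "CC"
  is_cc <- classes == positive
  cl <- sort(unique(labels))
  size <- as.vector(table(factor(labels, levels = cl)))
  cc_count <- vapply(cl, function(k) sum(is_cc[labels == k]), numeric(1))
  frac <- cc_count / size
  role <- ifelse(frac > 0.5 & frac >= purity_floor, "CC",
                 ifelse(1 - frac >= purity_floor, "non-CC", "unlabeled"))
  out <- data.frame(cluster = cl, size = size, cc_count = cc_count,
                    cc_fraction = frac, role = role, name = NA_character_,
                    stringsAsFactors = FALSE)
  cc_rows <- which(out$role == "CC")
  cc_rows <- cc_rows[order(-out$size[cc_rows])]
  out$name[cc_rows] <- paste0("CC-", seq_along(cc_rows))
  ncc_rows <- which(out$role == "non-CC")
  ncc_rows <- ncc_rows[order(-out$size[ncc_rows])]
  out$name[ncc_rows] <- if (length(ncc_rows) == 1L) "non-CC" else
    paste0("non-CC-", seq_along(ncc_rows))
  out
}

#' Read a code-to-category mapping table
#'
#' Delimited text with columns `code`, `domain`, `category` (comma or tab,
#' auto-detected). Each code maps to at most one category per domain.
#'
#' @param path file path.
#' @return data.frame of class `category_map`.
#' @export
read_category_map <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  map <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character")
  as_category_map(map)
}

#' @rdname read_category_map
#' @param map data.frame with columns `code`, `domain`, `category`.
#' @export
as_category_map <- function(map) {
  need <- c("code", "domain", "category")
  if (!all(need %in% names(map))) {
    stop("category map needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(map[, c("code", "domain")])) {
    stop("a code maps to more than one category within a domain", call. = FALSE)
  }
  structure(map[, need], class = c("category_map", "data.frame"))
}

#' Per-cluster category prevalence with chi-square comparisons
#'
#' For every named cluster and mapped category, counts the patients having
#' at least one qualifying event and formats `"N (P%)"`. Each CC cluster is
#' compared against the non-CC reference cluster per category by a 2x2
#' Pearson chi-square test (patients with vs without the category). Events
#' whose code has no mapping in their domain are skipped and tallied.
#'
#' @param events long event table (`patient_id`, `code`, `domain`, ...).
#'   Diagnosis codes are truncated to 3 characters before lookup.
#' @param map a `category_map`.
#' @param assignments data.frame with `patient_id` and `cluster`.
#' @param roles cluster role table from [label_cluster_roles()]; only
#'   clusters with a role name are reported and the `non-CC` cluster is the
#'   chi-square reference.
#' @param p_adjust multiple-testing adjustment passed to
#'   [stats::p.adjust()] (`"none"` by default; e.g. `"bonferroni"`).
#' @return object of class `prevalence_report`: data.frame with one row per
#'   (category, cluster): `domain`, `category`, `cluster_name`, `count`,
#'   `size`, `percentage`, `formatted`, and for CC clusters `chisq` and
#'   `p_value` (`p_display` formatted). Attribute `skipped_codes` tallies
#'   unmapped codes.
#' @export
prevalence_table <- function(events, map, assignments, roles,
                             p_adjust = "none") {
  stopifnot(is.data.frame(events), is.data.frame(assignments))
  map <- as_category_map(map)
  named <- roles[!is.na(roles$name), , drop = FALSE]
  if (!nrow(named)) stop("no named clusters to report", call. = FALSE)
  # patients with no events simply count as not having any category
  ev <- events
  ev$code_norm <- ifelse(ev$domain == "diagnosis",
                         truncate_icd10(ev$code), ev$code)
  key <- paste(ev$code_norm, ev$domain)
  map_key <- paste(map$code, map$domain)
  hit <- match(key, map_key)
  skipped <- table(key[is.na(hit)])
  ev <- ev[!is.na(hit), , drop = FALSE]
  ev$category <- map$category[hit[!is.na(hit)]]

  cluster_of <- setNames(assignments$cluster, assignments$patient_id)
  ev$cluster <- cluster_of[as.character(ev$patient_id)]
  ev <- ev[!is.na(ev$cluster) & ev$cluster %in% named$cluster, , drop = FALSE]

  cats <- unique(map[, c("domain", "category")])
  rows <- list()
  ref <- named[named$role == "non-CC", , drop = FALSE][1, ]
  for (ci in seq_len(nrow(cats))) {
    dom <- cats$domain[ci]; cat_name <- cats$category[ci]
    in_cat <- ev[ev$domain == dom & ev$category == cat_name, , drop = FALSE]
    ref_count <- NA_integer_
    for (ri in seq_len(nrow(named))) {
      k <- named$cluster[ri]
      size <- named$size[ri]
      count <- length(unique(in_cat$patient_id[in_cat$cluster == k]))
      if (identical(named$name[ri], ref$name)) ref_count <- count
      rows[[length(rows) + 1L]] <- data.frame(
        domain = dom, category = cat_name, cluster_name = named$name[ri],
        role = named$role[ri], count = count, size = size,
        percentage = round(100 * count / size, 2L),
        formatted = format_count_pct(count, size),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)

  out$chisq <- NA_real_
  out$p_value <- NA_real_
  if (!is.na(ref$name[1])) {
    ref_sizes <- ref$size
    for (i in which(out$role == "CC")) {
      ref_row <- out$cluster_name == ref$name & out$domain == out$domain[i] &
        out$category == out$category[i]
      rc <- out$count[ref_row][1]
      test <- try(chi_square_2x2(rc, ref_sizes - rc,
                                 out$count[i], out$size[i] - out$count[i]),
                  silent = TRUE)
      if (!inherits(test, "try-error")) {
        out$chisq[i] <- test$statistic
        out$p_value[i] <- test$p_value
      }
    }
  }
  if (p_adjust != "none") {
    sel <- !is.na(out$p_value)
    out$p_value[sel] <- stats::p.adjust(out$p_value[sel], method = p_adjust)
  }
  out$p_display <- ifelse(is.na(out$p_value), "", format_pvalue(out$p_value))
  structure(out, class = c("prevalence_report", "data.frame"),
            skipped_codes = skipped)
}

#' Render a prevalence report as a markdown-style wide table
#'
#' @param report a `prevalence_report`.
#' @return character vector of table lines (invisibly printed).
#' @export
render_prevalence <- function(report) {
  clusters <- unique(report$cluster_name)
  cats <- unique(report[, c("domain", "category")])
  header <- c("Category", clusters, "p value")
  lines <- paste0("| ", paste(header, collapse = " | "), " |")
  lines <- c(lines, paste0("|", paste(rep("---", length(header)),
                                      collapse = "|"), "|"))
  for (ci in seq_len(nrow(cats))) {
    sub <- report[report$domain == cats$domain[ci] &
                    report$category == cats$category[ci], , drop = FALSE]
    cells <- sub$formatted[match(clusters, sub$cluster_name)]
    pv <- sub$p_display[sub$p_display != ""]
    pcell <- if (length(pv) == 0) "" else if (length(unique(pv)) == 1L)
      unique(pv) else paste0("(", paste(pv, collapse = ", "), ")")
    lines <- c(lines, paste0("| ", paste(c(cats$category[ci], cells, pcell),
                                         collapse = " | "), " |"))
  }
  lines
}

#' Cohort demographic summary table
#'
#' Mean (SD) per group for numeric variables; count (percentage of
#' non-missing) per level for categorical variables, with unknowns reported
#' separately as bare counts. Percentage denominators exclude unknowns.
#' The SD of a single observation is reported blank.
#'
#' @param demographics data.frame, one row per patient.
#' @param group_col name of the grouping column (e.g. CC vs non-CC).
#' @param numeric_vars,categorical_vars variable names; defaults infer from
#'   column types (everything except `group_col`).
#' @return data.frame with columns `variable`, `level`, one formatted column
#'   per group.
#' @export
cohort_summary <- function(demographics, group_col = "class",
                           numeric_vars = NULL, categorical_vars = NULL) {
  stopifnot(group_col %in% names(demographics))
  g <- factor(demographics[[group_col]])
  vars <- setdiff(names(demographics), group_col)
  if (is.null(numeric_vars)) {
    numeric_vars <- vars[vapply(demographics[vars], is.numeric, logical(1))]
  }
  if (is.null(categorical_vars)) categorical_vars <- setdiff(vars, numeric_vars)
  groups <- levels(g)
  rows <- list()
  add_row <- function(variable, level, values) {
    rows[[length(rows) + 1L]] <<- c(list(variable = variable, level = level),
                                    setNames(as.list(values), groups))
  }
  for (v in numeric_vars) {
    vals <- vapply(groups, function(gr) {
      x <- demographics[[v]][g == gr]
      x <- x[!is.na(x)]
      if (length(x) == 0) return("")
      if (length(x) == 1L) return(sprintf("%.2f ()", mean(x)))
      sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
    }, character(1))
    add_row(v, "Mean (SD)", vals)
  }
  for (v in categorical_vars) {
    x <- demographics[[v]]
    known <- !is.na(x) & x != ""
    for (lev in sort(unique(x[known]))) {
      vals <- vapply(groups, function(gr) {
        denom <- sum(known & g == gr)
        if (denom == 0) return("0 (0%)")
        format_count_pct(sum(known & g == gr & x == lev), denom,
                         big_mark = ",")
      }, character(1))
      add_row(v, lev, vals)
    }
    if (any(!known)) {
      vals <- vapply(groups, function(gr) {
        u <- sum(!known & g == gr)
        if (u > 0) formatC(u, format = "d", big.mark = ",") else ""
      }, character(1))
      add_row(v, "Unknown", vals)
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}
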