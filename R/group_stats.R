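#' Kruskal-Wallis rank-sum test with tie correction
#'
#' Computed from first principles on midranks: with pooled sample size N,
#' group sizes n_i and mean group ranks Rbar_i,
#' \deqn{H_0 = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - (N+1)/2)^2}
#' divided by the tie correction \eqn{C = 1 - \sum_g (t_g^3 - t_g)/(N^3 - N)}
#' over tie groups of size t_g. When every observation is identical (C = 0)
#' the statistic is defined as H = 0 with p = 1. The p-value is the
#' upper-tail chi-square probability with k-1 degrees of freedom; an exact
#' permutation p-value is available for small samples via \code{exact =
#' TRUE} (full enumeration of group assignments when feasible, otherwise
#' Monte Carlo).
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty,
#'   pooled N >= 3).
#' @param exact also compute a permutation p-value.
#' @param max_enumeration largest number of distinct assignments enumerated
#'   exhaustively before falling back to Monte Carlo.
#' @param n_mc Monte Carlo permutations for large designs.
#' @return object of class \code{kruskal_wallis}: H, df, p (chi-square),
#'   tie_correction, n_per_group, and p_exact/exact_method when requested.
#' @export
kruskal_wallis <- function(groups, exact = FALSE, max_enumeration = 50000,
                           n_mc = 10000) {
  if (!is.list(groups) || length(groups) < 2)
    stop_config("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop_config("empty group")
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, function(g) any(!is.finite(g)), logical(1))))
    stop_config("observations must be finite numbers")
  n <- lengths(groups)
  N <- sum(n)
  if (N < 3) stop_config("need a pooled sample size of at least 3")
  k <- length(groups)
  g <- rep(seq_len(k), n)
  x <- unlist(groups, use.names = FALSE)

  H <- kw_statistic(x, g, k, N)
  res <- list(H = H$H, df = k - 1L,
              p = if (H$C == 0) 1 else pchisq(H$H, k - 1L, lower.tail = FALSE),
              tie_correction = H$C,
              n_per_group = n)
  if (H$C == 0) res$p <- 1

  if (exact) {
    perm <- kw_permutation_p(x, n, H$H, max_enumeration, n_mc)
    res$p_exact <- perm$p
    res$exact_method <- perm$method
  }
  structure(res, class = "kruskal_wallis")
}

# Tie-corrected H for observations x with group labels g.
kw_statistic <- function(x, g, k, N) {
  r <- rank(x)  # midranks
  Rbar <- tapply(r, g, mean)
  nn <- tabulate(g, nbins = k)
  H0 <- 12 / (N * (N + 1)) * sum(nn * (Rbar - (N + 1) / 2)^2)
  t <- table(x)
  C <- 1 - sum(t^3 - t) / (N^3 - N)
  list(H = if (C == 0) 0 else H0 / C, C = C)
}

# Permutation null of H under random reassignment of the pooled observations
# to groups of the observed sizes; p = P(H* >= H_obs), including the
# observed assignment.
kw_permutation_p <- function(x, n, H_obs, max_enumeration, n_mc) {
  N <- sum(n)
  k <- length(n)
  n_assign <- exp(lgamma(N + 1) - sum(lgamma(n + 1)))
  tol <- 1e-9
  if (n_assign <= max_enumeration) {
    assigns <- enumerate_assignments(seq_len(N), n)
    H_all <- vapply(assigns, function(idx) {
      g <- integer(N); g[unlist(idx)] <- rep(seq_len(k), n)
      kw_statistic(x, g, k, N)$H
    }, numeric(1))
    list(p = mean(H_all >= H_obs - tol), method = "enumeration")
  } else {
    H_mc <- vapply(seq_len(n_mc), function(i) {
      g <- sample(rep(seq_len(k), n))
      kw_statistic(x, g, k, N)$H
    }, numeric(1))
    list(p = (1 + sum(H_mc >= H_obs - tol)) / (n_mc + 1),
         method = "monte_carlo")
  }
}

# All ways to split `pool` into ordered groups of sizes n; returns a list of
# lists of index vectors.
enumerate_assignments <- function(pool, n) {
  if (length(n) == 1L) return(list(list(pool)))
  first <- utils::combn(pool, n[1], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- enumerate_assignments(setdiff(pool, f), n[-1])
    for (r in rest) out[[length(out) + 1L]] <- c(list(f), r)
  }
  out
}

#' @export
print.kruskal_wallis <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
              x$H, x$df, x$p))
  cat("  group sizes:", paste(x$n_per_group, collapse = ", "),
      sprintf("; tie correction C = %.4f\n", x$tie_correction))
  if (!is.null(x$p_exact))
    cat(sprintf("  exact permutation p = %.4g (%s)\n", x$p_exact,
                x$exact_method))
  invisible(x)
}

# ---- tumor growth tables ----------------------------------------------------

TK_GROWTH_GROUPS <- c("vehicle", "anti_PD1", "anti_CTLA4")

#' Read and validate an in vivo tumor-growth table
#'
#' CSV with columns \code{animal_id, group, day, volume_mm3}; one row per
#' animal per measured day. Animals that reach the humane endpoint simply
#' stop contributing rows (censoring by absence); volumes are accepted as
#' provided.
#'
#' @param path CSV path.
#' @param allowed_groups closed group vocabulary.
#' @return validated data.frame.
#' @export
read_tumor_growth <- function(path, allowed_groups = TK_GROWTH_GROUPS) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_tumor_growth(tab, allowed_groups)
}

validate_tumor_growth <- function(tab, allowed_groups = TK_GROWTH_GROUPS) {
  need <- c("animal_id", "group", "day", "volume_mm3")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_config("tumor-growth table is missing column(s): ",
                paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$group), allowed_groups)
  if (length(bad))
    stop_config("unknown group(s): ", paste(bad, collapse = ", "),
                "; allowed: ", paste(allowed_groups, collapse = ", "))
  if (any(tab$volume_mm3 < 0)) stop_config("volumes must be >= 0")
  if (any(tab$day < 0)) stop_config("days must be non-negative")
  if (anyDuplicated(tab[c("animal_id", "day")]))
    stop_config("more than one row per animal per day")
  tab
}

#' Percent tumor-volume reduction of a treated group versus control
#'
#' \code{100 * (1 - mean(treated) / mean(control))} over the animals still
#' measured at the requested day, with the contributing n per group reported
#' (per-day n shrinks as animals reach endpoint).
#'
#' @param table a tumor-growth data.frame (see [read_tumor_growth()]).
#' @param day measurement day.
#' @param treated_group,control_group group labels.
#' @return one-row data.frame: day, groups, means, n per group,
#'   percent_reduction.
#' @export
percent_reduction <- function(table, day, treated_group, control_group) {
  table <- validate_tumor_growth(table)
  tr <- table$volume_mm3[table$group == treated_group & table$day == day]
  ct <- table$volume_mm3[table$group == control_group & table$day == day]
  if (!length(tr))
    stop_config("no ", treated_group, " measurements at day ", day)
  if (!length(ct))
    stop_config("no ", control_group, " measurements at day ", day)
  if (mean(ct) == 0) stop_config("control mean volume is zero at day ", day)
  data.frame(day = day, treated_group = treated_group,
             control_group = control_group,
             n_treated = length(tr), n_control = length(ct),
             treated_mean_mm3 = mean(tr), control_mean_mm3 = mean(ct),
             percent_reduction = 100 * (1 - mean(tr) / mean(ct)),
             stringsAsFactors = FALSE)
}

#' Per-group per-day tumor-volume summary
#'
#' Means over the animals measured at each day; SE = sd/sqrt(n), NA for
#' single-animal days (flagged).
#'
#' @param table a tumor-growth data.frame.
#' @return data.frame: group, day, n, mean_volume_mm3, se_volume_mm3,
#'   qc_flags.
#' @export
group_timeseries_summary <- function(table) {
  table <- validate_tumor_growth(table)
  out <- do.call(rbind, lapply(
    split(table, list(table$group, table$day), drop = TRUE),
    function(d) data.frame(group = d$group[1], day = d$day[1],
                           n = nrow(d),
                           mean_volume_mm3 = mean(d$volume_mm3),
                           se_volume_mm3 = std_error(d$volume_mm3),
                           qc_flags = if (nrow(d) < 2) "se_undefined" else "",
                           stringsAsFactors = FALSE)))
  out <- out[order(out$group, out$day), ]
  rownames(out) <- NULL
  out
}

#' Per-day Kruskal-Wallis tests across groups
#'
#' Runs the tie-corrected test independently at every day (or timepoint),
#' mirroring per-day significance marks on trajectory plots, and additionally
#' reports Holm-adjusted p-values to expose the multiplicity across days.
#'
#' @param data long-format data.frame.
#' @param value_col,group_col,day_col column names.
#' @return data.frame: day, k, n_total, H, p, p_holm.
#' @export
kruskal_by_day <- function(data, value_col = "volume_mm3",
                           group_col = "group", day_col = "day") {
  stopifnot(all(c(value_col, group_col, day_col) %in% names(data)))
  days <- sort(unique(data[[day_col]]))
  rows <- lapply(days, function(d) {
    sub <- data[data[[day_col]] == d & !is.na(data[[value_col]]), ]
    groups <- split(sub[[value_col]], sub[[group_col]], drop = TRUE)
    if (length(groups) < 2 || sum(lengths(groups)) < 3) return(NULL)
    kw <- kruskal_wallis(groups)
    data.frame(day = d, k = length(groups), n_total = sum(lengths(groups)),
               H = kw$H, p = kw$p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(day = numeric(0), k = integer(0), n_total = integer(0),
                      H = numeric(0), p = numeric(0), p_holm = numeric(0)))
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$p, method = "holm")
  out
}
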