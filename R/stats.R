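#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' The group-comparison procedure used for replicate end-point measurements
#' (e.g. atom percent across strains or O2 levels): one-way analysis of
#' variance, Tukey's honestly-significant-difference pairwise test, and a
#' compact letter display in which two groups share no letter exactly when
#' they differ at level `alpha`. Letters are assigned by a greedy clique
#' cover over the graph of non-significant pairs, groups visited in
#' alphabetical order (deterministic output).
#'
#' Degenerate input (all observations identical across all groups) returns
#' `p_value = 1` and a single shared letter.
#'
#' @param groups Named list of numeric replicate vectors, >= 2 groups with
#'   >= 2 replicates each.
#' @param alpha Significance level for the letter display (default 0.05).
#'
#' @return A list with `means` (named), `F_statistic`, `p_value`,
#'   `tukey` (data.frame: pair, diff, p_adj), `letters` (named character).
#' @export
#' @examples
#' anova_tukey(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8)))
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- letters[seq_along(groups)]
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("each group needs at least two replicates", call. = FALSE)
  }
  gnames <- sort(names(groups))
  groups <- groups[gnames]
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(gnames, vapply(groups, length, 1L)), levels = gnames))
  means <- vapply(groups, mean, 1)

  if (stats::var(df$value) == 0) {
    pairs <- utils::combn(gnames, 2)
    tuk <- data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                      diff = 0, p_adj = 1)
    return(list(means = means, F_statistic = NaN, p_value = 1, tukey = tuk,
                letters = stats::setNames(rep("a", length(gnames)), gnames)))
  }

  fit <- stats::aov(value ~ group, data = df)
  anova_tab <- summary(fit)[[1]]
  Fstat <- anova_tab[["F value"]][1]
  pval <- anova_tab[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  tuk <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    p_adj = tk[, "p adj"], row.names = NULL)

  # non-significant-pairs graph -> greedy clique cover -> letters
  ns <- diag(TRUE, length(gnames))
  dimnames(ns) <- list(gnames, gnames)
  for (i in seq_len(nrow(tuk))) {
    gg <- strsplit(tuk$pair[i], "-", fixed = TRUE)[[1]]
    ns[gg[1], gg[2]] <- ns[gg[2], gg[1]] <- tuk$p_adj[i] >= alpha
  }
  letters_out <- stats::setNames(rep("", length(gnames)), gnames)
  covered_edge <- matrix(FALSE, length(gnames), length(gnames),
                         dimnames = list(gnames, gnames))
  letter_i <- 0
  repeat {
    # an uncovered requirement: an NS pair not yet sharing a letter, or a
    # group with no letter at all
    need <- which(ns & !covered_edge & upper.tri(ns), arr.ind = TRUE)
    lonely <- gnames[letters_out == ""]
    if (nrow(need) == 0 && length(lonely) == 0) break
    seed_members <- if (nrow(need) > 0) {
      gnames[sort(c(need[1, 1], need[1, 2]))]
    } else {
      lonely[1]
    }
    clique <- seed_members
    for (g in setdiff(gnames, clique)) {
      if (all(ns[g, clique])) clique <- c(clique, g)
    }
    clique <- sort(clique)
    letter_i <- letter_i + 1
    lab <- letters[letter_i]
    letters_out[clique] <- paste0(letters_out[clique], lab)
    covered_edge[clique, clique] <- TRUE
  }
  list(means = means, F_statistic = Fstat, p_value = pval, tukey = tuk,
       letters = letters_out)
}
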