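# Rank-based post hoc and factorial procedures used by the allometry module.
# Implemented here because the sampled field quantities (tuft circumferences,
# bark masses) are non-normal and heteroscedastic, so the comparisons use
# rank statistics throughout.

# Dunn's post hoc test of pairwise mean-rank differences after a
# Kruskal-Wallis omnibus, with the usual tie correction. Returns one row per
# pair with the z statistic and two-sided p-values (raw and Holm-adjusted).
.dunnTest <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  meanR <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (meanR[[i]] - meanR[[j]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
             z = z, p = p, p_adj = stats::p.adjust(p, "holm"))
}

# Aligned-rank-transform two-way ANOVA (Higgins/Wobbrock alignment): for each
# effect, responses are aligned by stripping every other estimated effect,
# ranked, and a standard factorial ANOVA is run on the ranks; only the row
# for the effect the data were aligned for is retained.
.artAnova <- function(y, f1, f2, names = c("f1", "f2")) {
  f1 <- as.factor(f1); f2 <- as.factor(f2)
  grand <- mean(y)
  cellMean <- ave(y, f1, f2)
  m1 <- ave(y, f1)
  m2 <- ave(y, f2)
  resid <- y - cellMean
  aligned <- list(resid + (m1 - grand),                    # main effect 1
                  resid + (m2 - grand),                    # main effect 2
                  resid + (cellMean - m1 - m2 + grand))    # interaction
  rows <- c(names[1], names[2], paste(names, collapse = ":"))
  out <- lapply(seq_along(aligned), function(k) {
    a <- anova(aov(rank(aligned[[k]]) ~ f1 * f2))
    rownames(a) <- sub("^f1:f2$", paste(names, collapse = ":"),
                       sub("^f2$", names[2], sub("^f1$", names[1],
                                                 rownames(a))))
    a[rows[k], c("Df", "F value", "Pr(>F)")]
  })
  res <- do.call(rbind, out)
  data.frame(effect = rows, df = res$Df, F = res$`F value`, p = res$`Pr(>F)`)
}
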