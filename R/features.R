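#' Per-chromosome sequence features
#'
#' Computes the feature row used in core-versus-accessory contrasts: gene
#' count and density (genes per 100 kb of chromosome length), TE fraction
#' (bases covered by the union of repeat intervals -- overlaps merged and
#' counted once), mean introns per gene (exon count minus one), mean gene
#' length, and the per-class composition of repeat-covered bases.
#'
#' @param chrom Chromosome identifier.
#' @param length Chromosome length (bp).
#' @param genes Data frame of this chromosome's genes with `start`, `end`
#'   (1-based, end-exclusive) and `n_exons`.
#' @param repeats Data frame of this chromosome's repeats with `start`,
#'   `end` (same convention) and `class`.
#' @return One-row data frame (class `feature_row`) plus a `te_composition`
#'   attribute with per-class proportions of repeat-covered bases.
#' @export
chromosome_features <- function(chrom, length, genes = NULL, repeats = NULL) {
  check_bounds <- function(df, what) {
    if (is.null(df) || nrow(df) == 0) return(invisible())
    bad <- which(df$start < 1 | df$end > length + 1 | df$end < df$start)
    if (length(bad) > 0) {
      id <- if (!is.null(df$gene_id)) df$gene_id[bad[1]] else
        sprintf("%s:%d-%d", chrom, df$start[bad[1]], df$end[bad[1]])
      stop(sprintf("%s record out of chromosome bounds: %s", what, id))
    }
  }
  check_bounds(genes, "gene")
  check_bounds(repeats, "repeat")

  n_genes <- if (is.null(genes)) 0L else nrow(genes)
  density <- n_genes / (length / 1e5)
  introns <- if (n_genes > 0) mean(genes$n_exons - 1) else NA_real_
  mean_len <- if (n_genes > 0) mean(genes$end - genes$start) else NA_real_

  te_frac <- 0
  comp <- setNames(numeric(length(TE_CLASSES) + 1),
                   c(TE_CLASSES, "other"))
  if (!is.null(repeats) && nrow(repeats) > 0) {
    ir <- IRanges::IRanges(repeats$start, repeats$end - 1L)
    union_bp <- sum(IRanges::width(IRanges::reduce(ir)))
    te_frac <- union_bp / length
    cls <- ifelse(repeats$class %in% TE_CLASSES, repeats$class, "other")
    for (cc in unique(cls)) {
      sel <- cls == cc
      bp <- sum(IRanges::width(IRanges::reduce(ir[sel])))
      comp[cc] <- bp
    }
    if (sum(comp) > 0) comp <- comp / sum(comp)
  }
  out <- data.frame(chrom = chrom, length = length, gene_count = n_genes,
                    gene_density = density, te_fraction = te_frac,
                    introns_per_gene = introns, mean_gene_length = mean_len,
                    stringsAsFactors = FALSE)
  attr(out, "te_composition") <- comp
  class(out) <- c("feature_row", class(out))
  out
}

#' Feature table for a whole genome set
#'
#' Applies [chromosome_features()] to every chromosome and attaches class
#' and group labels.
#'
#' @param lengths Named vector of chromosome lengths.
#' @param genes,repeats Annotation tables with a `chrom` column.
#' @param chromosomes Optional data frame with `chrom`, `group_label` (or
#'   `truth_group`) and `class` (or `kind`) used to label rows.
#' @return Data frame, one row per chromosome.
#' @export
feature_table <- function(lengths, genes = NULL, repeats = NULL,
                          chromosomes = NULL) {
  gsplit <- if (!is.null(genes)) split(genes, genes$chrom) else list()
  rsplit <- if (!is.null(repeats)) split(repeats, repeats$chrom) else list()
  rows <- lapply(names(lengths), function(ch) {
    fr <- chromosome_features(ch, lengths[[ch]], gsplit[[ch]], rsplit[[ch]])
    comp <- attr(fr, "te_composition")
    cbind(fr, as.data.frame(as.list(comp), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  if (!is.null(chromosomes)) {
    grp_col <- intersect(c("group_label", "truth_group"), names(chromosomes))[1]
    cls_col <- intersect(c("class", "kind"), names(chromosomes))[1]
    m <- match(out$chrom, chromosomes$chrom)
    out$group <- chromosomes[[grp_col]][m]
    cls <- chromosomes[[cls_col]][m]
    out$class <- ifelse(cls %in% c("core", "cc"), "core",
                        ifelse(cls %in% c("accessory", "ac"), "accessory", cls))
  }
  rownames(out) <- NULL
  out
}

#' One-way ANOVA contrast between groups of chromosomes
#'
#' Classical one-way F statistic `(SSB/dfB) / (SSW/dfW)` with its p-value,
#' used for core-versus-accessory feature contrasts. Degenerate inputs are
#' resolved explicitly: all values identical gives F = 0 with p = 1; zero
#' within-group variance with differing group means gives F = Inf with
#' p = 0.
#'
#' @param values Numeric vector of per-chromosome feature values.
#' @param groups Factor or character vector of group labels.
#' @return List (class `anova_contrast`): `means`, `F`, `df` (between,
#'   within), `p`.
#' @export
compare_groups_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  ns <- table(groups)
  if (any(ns < 1) || sum(ns) - nlevels(groups) < 1) {
    stop("need at least one group with two values")
  }
  means <- tapply(values, groups, mean)
  dfb <- nlevels(groups) - 1L
  dfw <- length(values) - nlevels(groups)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  ssb <- sum(ns * (means - mean(values))^2)
  if (ssw == 0 && ssb == 0) {
    f <- 0; p <- 1
  } else if (ssw == 0) {
    f <- Inf; p <- 0
  } else {
    fit <- anova(lm(values ~ groups))
    f <- fit$`F value`[1]
    p <- fit$`Pr(>F)`[1]
  }
  structure(list(means = means, F = f, df = c(between = dfb, within = dfw),
                 p = p),
            class = "anova_contrast")
}

#' @export
print.anova_contrast <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p))
  print(round(x$means, 3))
  invisible(x)
}

#' TE-class composition contrast between chromosome classes
#'
#' For each chromosome class (core / accessory), the proportion of
#' repeat-covered bases contributed by each TE class, with the
#' accessory-to-core enrichment ratio.
#'
#' @param repeats Repeat table with `chrom`, `start`, `end`, `class`.
#' @param chrom_class Named vector mapping chromosome id to `"core"` /
#'   `"accessory"`.
#' @return Data frame: `te_class`, `core`, `accessory`, `ratio`.
#' @export
te_class_composition <- function(repeats, chrom_class) {
  comp_for <- function(cls) {
    sel <- repeats[chrom_class[repeats$chrom] == cls, , drop = FALSE]
    out <- setNames(numeric(length(TE_CLASSES) + 1), c(TE_CLASSES, "other"))
    if (nrow(sel) == 0) return(out)
    rc <- ifelse(sel$class %in% TE_CLASSES, sel$class, "other")
    for (cc in unique(rc)) {
      rows <- sel[rc == cc, ]
      bp <- sum(vapply(split(rows, rows$chrom), function(df) {
        sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(df$start, df$end - 1L))))
      }, numeric(1)))
      out[cc] <- bp
    }
    if (sum(out) > 0) out / sum(out) else out
  }
  core <- comp_for("core")
  acc <- comp_for("accessory")
  data.frame(te_class = names(core), core = unname(core),
             accessory = unname(acc),
             ratio = unname(ifelse(core > 0, acc / core, NA_real_)),
             stringsAsFactors = FALSE)
}

#' Ordinary least-squares regression of genome size on a predictor
#'
#' Fits `y ~ x` by OLS and reports slope, intercept and the coefficient of
#' determination, as used for the relation between accessory-chromosome
#' content (or core repeat content) and total genome size.
#'
#' @param x Predictor (e.g. per-haplotype accessory chromosome size).
#' @param y Response (e.g. per-haplotype genome size).
#' @return List: `slope`, `intercept`, `r_squared`, `n`; `zero_variance`
#'   is `TRUE` when `y` is constant (R-squared reported as 0 and flagged).
#' @export
size_regression <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (sd(x) == 0) stop("`x` is constant; regression undefined")
  if (sd(y) == 0) {
    return(list(slope = 0, intercept = y[1], r_squared = 0, n = length(x),
                zero_variance = TRUE))
  }
  fit <- lm(y ~ x)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - sse / sst,
       n = length(x), zero_variance = FALSE)
}
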