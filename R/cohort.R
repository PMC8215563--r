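# Exposure coding (BMI bands, dietary-fat tertile bands, genotype classes)
# and descriptive cohort tables.

#' Categorize BMI into WHO-style bands
#'
#' `normal` for 19 <= BMI < 25, `overweight` for 25 <= BMI < 30, `obese` for
#' BMI >= 30. Values below 19 fall outside all bands and are flagged as
#' `underweight` with a warning rather than silently binned.
#'
#' @param bmi numeric vector, kg/m^2 (> 0).
#' @return factor with levels `normal`, `overweight`, `obese`, `underweight`.
#' @examples
#' categorize_bmi(c(24.10, 25, 30))
#' @export
categorize_bmi <- function(bmi) {
  if (!is.numeric(bmi) || any(bmi[!is.na(bmi)] <= 0))
    stop("bmi must be positive (kg/m^2)")
  out <- ifelse(is.na(bmi), NA_character_,
         ifelse(bmi < 19, "underweight",
         ifelse(bmi < 25, "normal",
         ifelse(bmi < 30, "overweight", "obese"))))
  n_under <- sum(out == "underweight", na.rm = TRUE)
  if (n_under > 0)
    warning(n_under, " BMI value(s) below 19 kg/m^2 fall outside the ",
            "normal/overweight/obese bands; flagged as 'underweight'")
  factor(out, levels = c("normal", "overweight", "obese", "underweight"))
}

#' Categorize percentage of meal energy from fat into tertile bands
#'
#' `low` below 30%, `medium` from 30% to below 35%, `high` at 35% and above.
#' (The upper band is taken as closed at 35% so that the three bands cover
#' the whole range.)
#'
#' @param fat_pct numeric vector, percent of meal energy from fat in
#'   \[0, 100\].
#' @return factor with levels `low`, `medium`, `high`.
#' @examples
#' categorize_fat(c(29.9, 30, 35))
#' @export
categorize_fat <- function(fat_pct) {
  ok <- is.na(fat_pct) | (fat_pct >= 0 & fat_pct <= 100)
  if (!is.numeric(fat_pct) || !all(ok))
    stop("fat_pct must be in [0, 100]")
  out <- ifelse(is.na(fat_pct), NA_character_,
         ifelse(fat_pct < 30, "low",
         ifelse(fat_pct < 35, "medium", "high")))
  factor(out, levels = c("low", "medium", "high"))
}

#' Minor allele frequency from genotype counts
#'
#' Frequency of the A allele of a biallelic SNP (here FTO rs9939609, alleles
#' T and A): `(2 n_AA + n_AT) / (2 n_total)`. The A allele is treated as the
#' minor allele by convention regardless of its frequency.
#'
#' @param counts named numeric vector or list of genotype counts with any of
#'   the names `T/T`, `A/T`, `A/A` (missing genotypes count as 0), or a
#'   factor/character vector of genotype labels to be tabulated.
#' @return allele frequency in \[0, 1\].
#' @examples
#' compute_maf(c("T/T" = 14, "A/T" = 32, "A/A" = 8))   # 0.444...
#' @export
compute_maf <- function(counts) {
  if (is.factor(counts) || is.character(counts))
    counts <- table(counts)
  counts <- unlist(counts)
  if (length(counts) == 0L || sum(counts) < 1)
    stop("need at least one genotyped individual")
  bad <- setdiff(names(counts), c("T/T", "A/T", "A/A"))
  if (length(bad))
    stop("unknown genotype label(s): ", paste(bad, collapse = ", "))
  get <- function(g) if (g %in% names(counts)) counts[[g]] else 0
  (2 * get("A/A") + get("A/T")) / (2 * sum(counts))
}

#' Descriptive cohort table
#'
#' N, mean (SD) and category counts/percentages for a participant exposure
#' table, optionally joined with per-meal summaries for average meal duration
#' and starting weight. Recognized columns of `exposures`: `sex` (character /
#' factor, percentage of the first-sorted level reported as-is per level),
#' `age`, `bmi`, `genotype`, `fat_pct`; all optional.
#'
#' @param exposures data frame with `participant_id` and any of the columns
#'   above.
#' @param summaries optional data frame from [summarize_meals()].
#' @return list of class `descriptive_table`: `continuous` (variable, n,
#'   mean, sd), `categories` (variable, level, count, percent), `maf`
#'   (A-allele frequency, or `NA` without genotypes), `n_participants`.
#' @export
descriptive_table <- function(exposures, summaries = NULL) {
  stopifnot(is.data.frame(exposures), nrow(exposures) > 0,
            "participant_id" %in% names(exposures))
  cont <- list(); cats <- list()
  add_cont <- function(name, x) {
    x <- x[!is.na(x)]
    if (length(x))
      cont[[length(cont) + 1L]] <<- data.frame(
        variable = name, n = length(x), mean = mean(x), sd = sd(x))
  }
  add_cat <- function(name, f) {
    f <- f[!is.na(f)]
    if (!length(f)) return()
    tab <- table(f)
    tab <- tab[tab > 0]          # published-style tables omit empty classes
    cats[[length(cats) + 1L]] <<- data.frame(
      variable = name, level = names(tab), count = as.integer(tab),
      percent = 100 * as.integer(tab) / sum(tab), row.names = NULL)
  }
  if ("sex" %in% names(exposures)) add_cat("sex", factor(exposures$sex))
  if ("age" %in% names(exposures)) add_cont("age_years", exposures$age)
  if (!is.null(summaries)) {
    add_cont("meal_duration_s", summaries$duration)
    add_cont("start_weight_g", summaries$start_weight)
  }
  maf <- NA_real_
  if ("bmi" %in% names(exposures)) {
    add_cont("bmi_kg_m2", exposures$bmi)
    add_cat("bmi_class", suppressWarnings(categorize_bmi(exposures$bmi)))
  }
  if ("genotype" %in% names(exposures)) {
    g <- factor(exposures$genotype, levels = c("T/T", "A/T", "A/A"))
    add_cat("genotype", g)
    if (any(!is.na(g))) maf <- compute_maf(g[!is.na(g)])
  }
  if ("fat_pct" %in% names(exposures)) {
    add_cont("fat_pct", exposures$fat_pct)
    add_cat("fat_class", categorize_fat(exposures$fat_pct))
  }
  out <- list(
    continuous = if (length(cont)) do.call(rbind, cont) else
      data.frame(variable = character(), n = integer(), mean = numeric(),
                 sd = numeric()),
    categories = if (length(cats)) do.call(rbind, cats) else
      data.frame(variable = character(), level = character(),
                 count = integer(), percent = numeric()),
    maf = maf,
    n_participants = nrow(exposures)
  )
  class(out) <- "descriptive_table"
  out
}

#' @exportS3Method base::print
print.descriptive_table <- function(x, digits = 2, ...) {
  cat("Cohort characteristics (N =", x$n_participants, ")\n")
  if (nrow(x$continuous)) {
    cat("\n  Variable              N    Mean (SD)\n")
    for (i in seq_len(nrow(x$continuous)))
      cat(sprintf("  %-20s %4d  %.*f (%.*f)\n", x$continuous$variable[i],
                  x$continuous$n[i], digits, x$continuous$mean[i], digits,
                  x$continuous$sd[i]))
  }
  if (nrow(x$categories)) {
    cat("\n  Variable / level          N    %\n")
    for (i in seq_len(nrow(x$categories)))
      cat(sprintf("  %-14s %-10s %4d  %.*f\n", x$categories$variable[i],
                  x$categories$level[i], x$categories$count[i], digits,
                  x$categories$percent[i]))
  }
  if (!is.na(x$maf)) cat(sprintf("\n  MAF (A allele): %.2f\n", x$maf))
  invisible(x)
}
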