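#' Complement DNA alleles
#'
#' Base-wise Watson-Crick complement, used to test whether two GWAS report a
#' variant on opposite strands.
#'
#' @param allele character vector of alleles composed of A/C/G/T.
#' @return Complemented alleles (same lengths).
#' @examples
#' complement_alleles(c("A", "AG"))
#' @export
complement_alleles <- function(allele) {
  allele <- toupper(as.character(allele))
  if (any(is.na(allele)) || any(!grepl("^[ACGT]+$", allele))) {
    stop("alleles must be nonempty strings over A/C/G/T", call. = FALSE)
  }
  chartr("ACGT", "TGCA", allele)
}

#' Is a biallelic SNP palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so strand flips cannot be
#' detected from the allele labels alone.
#'
#' @param effect_allele,other_allele single-base alleles (vectorized).
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(as.character(effect_allele))
  oa <- toupper(as.character(other_allele))
  single <- nchar(ea) == 1L & nchar(oa) == 1L &
    grepl("^[ACGT]$", ea) & grepl("^[ACGT]$", oa)
  single & oa == chartr("ACGT", "TGCA", ea)
}

.harmonized_cols <- c("SNP", "EA", "BETA_EXP", "SE_EXP", "BETA_OUT", "SE_OUT",
                      "STATUS")
.usable_statuses <- c("kept", "allele_flipped", "strand_flipped")
.harmonize_statuses <- c(.usable_statuses,
                         "dropped_palindromic", "dropped_incompatible")

#' Harmonize one exposure/outcome record pair
#'
#' Expresses the outcome association on the exposure's effect allele. Exact
#' allele matches are kept; swapped effect/other alleles negate the outcome
#' beta (and complement its EAF); alleles matching only after strand
#' complement are treated as a strand flip (with the swap rule applied after
#' complementing). Palindromic SNPs are oriented by allele frequency when
#' both EAFs are informative (outside `0.5 +/- palindromic_eaf_window`),
#' otherwise dropped. Indels, multi-base alleles and irreconcilable pairs
#' are dropped as incompatible. Standard errors are never altered.
#'
#' @param exposure_rec,outcome_rec one-row data frames (or lists) with the
#'   canonical summary-statistic fields, same `SNP`.
#' @param palindromic_eaf_window half-width of the EAF ambiguity zone around
#'   0.5 within which a palindromic SNP cannot be oriented (default 0.08).
#' @return One-row data frame with columns `SNP`, `EA`, `BETA_EXP`, `SE_EXP`,
#'   `BETA_OUT`, `SE_OUT`, `STATUS`. Dropped rows carry `NA` betas.
#' @export
harmonize_pair <- function(exposure_rec, outcome_rec,
                           palindromic_eaf_window = 0.08) {
  e <- as.list(exposure_rec)
  o <- as.list(outcome_rec)
  if (!identical(as.character(e$SNP), as.character(o$SNP))) {
    stop("variant_id mismatch: ", e$SNP, " vs ", o$SNP, call. = FALSE)
  }
  w <- palindromic_eaf_window
  if (!is_scalar_number(w) || w < 0 || w >= 0.5) {
    stop("`palindromic_eaf_window` must lie in [0, 0.5)", call. = FALSE)
  }

  res <- function(status, beta_out = NA_real_, se_out = NA_real_, ea = e$EA,
                  beta_exp = e$BETA, se_exp = e$SE) {
    usable <- status %in% .usable_statuses
    data.frame(SNP = as.character(e$SNP), EA = ea,
               BETA_EXP = if (usable) beta_exp else NA_real_,
               SE_EXP = if (usable) se_exp else NA_real_,
               BETA_OUT = beta_out, SE_OUT = se_out,
               STATUS = status, stringsAsFactors = FALSE)
  }

  eea <- toupper(e$EA); eoa <- toupper(e$OA)
  oea <- toupper(o$EA); ooa <- toupper(o$OA)
  biallelic_snp <- all(nchar(c(eea, eoa, oea, ooa)) == 1L) &&
    all(grepl("^[ACGT]$", c(eea, eoa, oea, ooa)))
  if (!biallelic_snp) return(res("dropped_incompatible"))

  if (is_palindromic(eea, eoa)) {
    # Strand is unresolvable from labels; use EAF on both sides.
    same <- oea == eea && ooa == eoa
    swapped <- oea == eoa && ooa == eea
    if (!same && !swapped) return(res("dropped_incompatible"))
    eaf_e <- suppressWarnings(as.numeric(e$EAF))
    eaf_o <- suppressWarnings(as.numeric(o$EAF))
    if (swapped && !is.na(eaf_o)) eaf_o <- 1 - eaf_o
    informative <- !is.na(eaf_e) && !is.na(eaf_o) &&
      abs(eaf_e - 0.5) > w && abs(eaf_o - 0.5) > w
    if (!informative) return(res("dropped_palindromic"))
    beta_out <- if (swapped) -o$BETA else o$BETA
    status <- if (swapped) "allele_flipped" else "kept"
    if ((eaf_e - 0.5) * (eaf_o - 0.5) < 0) {
      # Frequencies disagree: the outcome labels are on the opposite strand,
      # which for a palindrome silently swaps effect and other allele.
      beta_out <- -beta_out
      status <- "strand_flipped"
    }
    return(res(status, beta_out = beta_out, se_out = o$SE))
  }

  if (oea == eea && ooa == eoa) {
    return(res("kept", beta_out = o$BETA, se_out = o$SE))
  }
  if (oea == eoa && ooa == eea) {
    return(res("allele_flipped", beta_out = -o$BETA, se_out = o$SE))
  }
  cea <- complement_alleles(oea); coa <- complement_alleles(ooa)
  if (cea == eea && coa == eoa) {
    return(res("strand_flipped", beta_out = o$BETA, se_out = o$SE))
  }
  if (cea == eoa && coa == eea) {
    return(res("strand_flipped", beta_out = -o$BETA, se_out = o$SE))
  }
  res("dropped_incompatible")
}

#' Harmonize an exposure study set against an outcome study set
#'
#' Intersects the two sets on variant ID, applies [harmonize_pair()] to each
#' shared variant in exposure order, and returns the usable instruments
#' (kept or flipped) as a `harmonized_set`. The harmonization audit (one
#' entry per exposure instrument: a harmonization status or
#' `absent_outcome`) is attached as attribute `audit`, and dropped rows as
#' attribute `dropped`.
#'
#' @param exposure exposure [study_set()] of instruments.
#' @param outcome outcome [study_set()].
#' @param palindromic_eaf_window see [harmonize_pair()].
#' @return Data frame of class `harmonized_set` with columns `SNP`, `EA`,
#'   `BETA_EXP`, `SE_EXP`, `BETA_OUT`, `SE_OUT`, `STATUS`, and attributes
#'   `exposure_name`, `outcome_name`, `audit`, `dropped`.
#' @export
harmonize_sets <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "study_set"), inherits(outcome, "study_set"))
  if (attr(exposure, "role") != "exposure" || attr(outcome, "role") != "outcome") {
    stop("`exposure` must have role exposure and `outcome` role outcome",
         call. = FALSE)
  }
  exp_name <- attr(exposure, "trait_name")
  out_name <- attr(outcome, "trait_name")
  shared <- exposure$SNP[exposure$SNP %in% outcome$SNP]
  if (length(shared) == 0L) {
    stop("no shared variants between exposure '", exp_name,
         "' and outcome '", out_name, "'", call. = FALSE)
  }
  rows <- lapply(shared, function(id) {
    harmonize_pair(exposure[exposure$SNP == id, ],
                   outcome[outcome$SNP == id, ],
                   palindromic_eaf_window = palindromic_eaf_window)
  })
  h <- do.call(rbind, rows)

  audit_status <- c(stats::setNames(h$STATUS, h$SNP),
                    stats::setNames(rep("absent_outcome",
                                        sum(!(exposure$SNP %in% outcome$SNP))),
                                    setdiff(exposure$SNP, outcome$SNP)))
  audit <- data.frame(SNP = exposure$SNP,
                      STATUS = unname(audit_status[exposure$SNP]),
                      stringsAsFactors = FALSE)
  counts <- table(factor(audit$STATUS,
                         levels = c(.harmonize_statuses, "absent_outcome")))
  message("harmonization audit ", exp_name, " -> ", out_name, ": ",
          paste(names(counts)[counts > 0], counts[counts > 0],
                sep = "=", collapse = ", "))

  usable <- h[h$STATUS %in% .usable_statuses, , drop = FALSE]
  dropped <- h[!(h$STATUS %in% .usable_statuses), , drop = FALSE]
  if (nrow(usable) == 0L) {
    stop("no usable instruments after harmonizing '", exp_name,
         "' against '", out_name, "'", call. = FALSE)
  }
  rownames(usable) <- NULL
  harmonized_set(usable, exposure_name = exp_name, outcome_name = out_name,
                 audit = audit, dropped = dropped)
}

#' Construct a harmonized instrument set
#'
#' @param data data frame with columns `SNP`, `BETA_EXP`, `SE_EXP`,
#'   `BETA_OUT`, `SE_OUT` and optionally `EA`, `STATUS`.
#' @param exposure_name,outcome_name trait labels.
#' @param audit,dropped optional audit metadata (see [harmonize_sets()]).
#' @return Data frame of class `harmonized_set`.
#' @export
harmonized_set <- function(data, exposure_name = "exposure",
                           outcome_name = "outcome", audit = NULL,
                           dropped = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- c("SNP", "BETA_EXP", "SE_EXP", "BETA_OUT", "SE_OUT")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("harmonized set missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"EA" %in% names(data)) data$EA <- rep(NA_character_, nrow(data))
  if (!"STATUS" %in% names(data)) data$STATUS <- rep("kept", nrow(data))
  for (col in c("BETA_EXP", "SE_EXP", "BETA_OUT", "SE_OUT")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  ok <- data$STATUS %in% .usable_statuses
  if (any(ok & (is.na(data$SE_EXP) | data$SE_EXP <= 0 |
                is.na(data$SE_OUT) | data$SE_OUT <= 0))) {
    stop("usable instruments must have positive SE_EXP and SE_OUT",
         call. = FALSE)
  }
  rownames(data) <- NULL
  structure(data[, c("SNP", "EA", "BETA_EXP", "SE_EXP", "BETA_OUT", "SE_OUT",
                     "STATUS")],
            exposure_name = exposure_name, outcome_name = outcome_name,
            audit = audit, dropped = dropped,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s, %d usable instrument(s)\n",
              attr(x, "exposure_name"), attr(x, "outcome_name"),
              sum(x$STATUS %in% .usable_statuses)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}

# Usable rows of a harmonized set as a plain data frame.
usable_instruments <- function(h) {
  h <- as.data.frame(h)
  h[h$STATUS %in% .usable_statuses, , drop = FALSE]
}

#' Write / read a harmonized instrument set as TSV
#'
#' The on-disk format is the regression-fixture format for full analyses:
#' columns `SNP`, `EA`, `BETA_EXP`, `SE_EXP`, `BETA_OUT`, `SE_OUT`, `STATUS`.
#'
#' @param h a `harmonized_set`.
#' @param path file path.
#' @return `path` (write) or a `harmonized_set` (read).
#' @export
write_harmonized <- function(h, path) {
  stopifnot(inherits(h, "harmonized_set"))
  utils::write.table(as.data.frame(h)[, .harmonized_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_harmonized
#' @param exposure_name,outcome_name trait labels for the read set.
#' @export
read_harmonized <- function(path, exposure_name = "exposure",
                            outcome_name = "outcome") {
  data <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  harmonized_set(data, exposure_name = exposure_name,
                 outcome_name = outcome_name)
}
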