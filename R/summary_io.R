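#' @title GWAS summary-statistic tables
#' @description Canonical column names for per-SNP summary statistics used
#'   throughout the package: `SNP` (rsID), `CHR`, `POS` (1-based), `EA`
#'   (effect allele), `OA` (other allele), `EAF` (effect-allele frequency),
#'   `BETA` (per-allele effect, log-odds for binary traits and SD units for
#'   standardized metabolites), `SE`, `P`.
#' @name sumstats-format
NULL

.sumstats_required <- c("SNP", "EA", "OA", "BETA", "SE", "P")
.sumstats_optional <- c("CHR", "POS", "EAF")
.sumstats_cols <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P")

#' Construct a study set of per-SNP associations
#'
#' A `study_set` is a validated data frame of one GWAS's per-SNP summary
#' statistics for a single trait, playing either the exposure or the outcome
#' role in a two-sample Mendelian randomization analysis.
#'
#' @param data data frame with columns `SNP`, `EA`, `OA`, `BETA`, `SE`, `P`
#'   and optionally `CHR`, `POS`, `EAF`.
#' @param trait_name trait label, e.g. `"glutamate"` or `"AD"`.
#' @param role `"exposure"` or `"outcome"`.
#' @param strict if `TRUE` (default) any invalid row is an error naming the
#'   offending rows; if `FALSE` invalid rows are dropped with a warning.
#' @return A data frame of class `study_set` with attributes `trait_name`
#'   and `role`. Alleles are uppercased; variant IDs are unique.
#' @export
study_set <- function(data, trait_name, role = c("exposure", "outcome"),
                      strict = TRUE) {
  role <- match.arg(role)
  if (!is.character(trait_name) || length(trait_name) != 1L || !nzchar(trait_name)) {
    stop("`trait_name` must be a nonempty string", call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.sumstats_required, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(.sumstats_optional, names(data))) {
    data[[col]] <- rep(NA, nrow(data))
  }
  data <- data[, .sumstats_cols]
  data$SNP <- as.character(data$SNP)
  data$EA <- toupper(as.character(data$EA))
  data$OA <- toupper(as.character(data$OA))
  data$CHR <- as.character(data$CHR)
  for (col in c("POS", "EAF", "BETA", "SE", "P")) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }

  bad <- validate_sumstats_rows(data)
  if (any(bad != "")) {
    idx <- which(bad != "")
    msgs <- paste0("row ", idx, ": ", bad[idx])
    if (strict) {
      stop("invalid summary-statistic rows in '", trait_name, "':\n  ",
           paste(msgs, collapse = "\n  "), call. = FALSE)
    }
    warning("dropping ", length(idx), " invalid row(s) in '", trait_name,
            "':\n  ", paste(msgs, collapse = "\n  "), call. = FALSE)
    data <- data[bad == "", , drop = FALSE]
  }
  if (anyDuplicated(data$SNP)) {
    dup <- unique(data$SNP[duplicated(data$SNP)])
    stop("duplicated variant_id(s) in '", trait_name, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0L) {
    warning("study set '", trait_name, "' has 0 records", call. = FALSE)
  }
  rownames(data) <- NULL
  structure(data, trait_name = trait_name, role = role,
            class = c("study_set", "data.frame"))
}

# One message per row; "" means the row is valid.
validate_sumstats_rows <- function(data) {
  msg <- character(nrow(data))
  add <- function(cond, text) {
    cond[is.na(cond)] <- FALSE
    ifelse(cond & msg == "", text, msg)
  }
  msg <- add(is.na(data$SNP) | !nzchar(data$SNP), "empty variant_id")
  msg <- add(!grepl("^[ACGT]+$", data$EA), "effect allele not A/C/G/T")
  msg <- add(!grepl("^[ACGT]+$", data$OA), "other allele not A/C/G/T")
  msg <- add(data$EA == data$OA, "effect_allele equals other_allele")
  msg <- add(is.na(data$BETA), "malformed beta")
  msg <- add(is.na(data$SE) | data$SE <= 0, "se must be > 0")
  msg <- add(is.na(data$P) | data$P <= 0 | data$P > 1, "p-value outside (0,1]")
  msg <- add(!is.na(data$EAF) & (data$EAF < 0 | data$EAF > 1),
             "eaf outside [0,1]")
  msg <- add(!is.na(data$POS) & data$POS < 1, "pos must be >= 1")
  msg
}

#' @export
print.study_set <- function(x, ...) {
  cat(sprintf("<study_set> %s (%s), %d variant(s)\n",
              attr(x, "trait_name"), attr(x, "role"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text table with a header, renames source columns to the
#' canonical names via `column_map`, and validates every row.
#'
#' @param path file path.
#' @param trait_name,role passed to [study_set()].
#' @param column_map optional named character vector mapping canonical names
#'   to source headers, e.g. `c(SNP = "rsid", BETA = "Effect")`; canonical
#'   names already present need not be mapped.
#' @param delim field delimiter, tab by default.
#' @param strict passed to [study_set()].
#' @return A [study_set()].
#' @export
read_summary_table <- function(path, trait_name, role = c("exposure", "outcome"),
                               column_map = NULL, delim = "\t", strict = TRUE) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "",
                           colClasses = "character")
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(!nzchar(names(column_map)))) {
      stop("`column_map` must be a named vector (canonical = source)",
           call. = FALSE)
    }
    unknown <- setdiff(names(column_map), .sumstats_cols)
    if (length(unknown)) {
      stop("`column_map` has non-canonical target name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent)) {
      stop("column(s) named in `column_map` not found in ", path, ": ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  study_set(raw, trait_name = trait_name, role = role, strict = strict)
}

#' Write a study set as a canonical TSV
#'
#' @param s a [study_set()].
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(s, path, delim = "\t") {
  stopifnot(inherits(s, "study_set"))
  utils::write.table(as.data.frame(s), path, sep = delim, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Select instruments by association p-value
#'
#' Keeps exposure variants with `P <= p_threshold`, in their original order.
#' Typical thresholds are genome-wide significance (`5e-8`) and, for traits
#' with no genome-wide signal, suggestive significance (`5e-6`).
#'
#' @param s an exposure [study_set()].
#' @param p_threshold positive significance threshold.
#' @return The filtered [study_set()].
#' @export
select_instruments <- function(s, p_threshold) {
  stopifnot(inherits(s, "study_set"))
  if (attr(s, "role") != "exposure") {
    stop("instrument selection applies to an exposure study set", call. = FALSE)
  }
  if (!is_scalar_number(p_threshold) || p_threshold <= 0) {
    stop("`p_threshold` must be a positive number", call. = FALSE)
  }
  keep <- s$P <= p_threshold
  out <- s[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no variants pass P <= ", format(p_threshold), " for '",
            attr(s, "trait_name"), "'", call. = FALSE)
  }
  structure(out, trait_name = attr(s, "trait_name"), role = "exposure",
            class = c("study_set", "data.frame"))
}

#' Read a proxy-substitution map
#'
#' A proxy map lists, for instruments missing from the outcome GWAS, linked
#' variants (and their LD r-squared with the missing instrument) that may
#' stand in for them. Columns: `MISSING_SNP`, `PROXY_SNP`, `R2`.
#'
#' @param path TSV path.
#' @return data frame with the three columns above.
#' @export
read_proxy_map <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  validate_proxy_map(pm)
}

validate_proxy_map <- function(proxy_map) {
  proxy_map <- as.data.frame(proxy_map, stringsAsFactors = FALSE)
  need <- c("MISSING_SNP", "PROXY_SNP", "R2")
  missing_cols <- setdiff(need, names(proxy_map))
  if (length(missing_cols)) {
    stop("proxy map missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  proxy_map$R2 <- as.numeric(proxy_map$R2)
  if (any(is.na(proxy_map$R2) | proxy_map$R2 < 0 | proxy_map$R2 > 1)) {
    stop("proxy map R2 values must lie in [0,1]", call. = FALSE)
  }
  proxy_map[, need]
}

#' Substitute LD proxies for instruments missing from the outcome GWAS
#'
#' Exposure instruments absent from the outcome study set are replaced by a
#' proxy variant when the supplied map links them with r-squared at or above
#' `r2_min` and the proxy itself is present in the outcome. The first
#' qualifying map entry per missing instrument is used; alternatives are
#' logged. Instruments that cannot be resolved are dropped with a count.
#' LD computation itself is out of scope: the map is user-supplied.
#'
#' @param exposure exposure [study_set()] of selected instruments.
#' @param outcome outcome [study_set()].
#' @param proxy_map data frame with columns `MISSING_SNP`, `PROXY_SNP`, `R2`
#'   (see [read_proxy_map()]), or `NULL` for no substitution.
#' @param r2_min minimum LD r-squared for an acceptable proxy (default 0.8).
#' @return The exposure [study_set()] with unresolvable instruments removed
#'   and proxied instruments renamed to the proxy's variant ID; the
#'   substitution log is attached as attribute `proxy_log`.
#' @export
apply_proxy_map <- function(exposure, outcome, proxy_map, r2_min = 0.8) {
  stopifnot(inherits(exposure, "study_set"), inherits(outcome, "study_set"))
  out <- as.data.frame(exposure)
  missing_ids <- setdiff(out$SNP, outcome$SNP)
  log <- data.frame(MISSING_SNP = character(), PROXY_SNP = character(),
                    R2 = numeric(), ACTION = character(),
                    stringsAsFactors = FALSE)
  if (length(missing_ids)) {
    proxy_map <- if (is.null(proxy_map)) {
      data.frame(MISSING_SNP = character(), PROXY_SNP = character(),
                 R2 = numeric())
    } else {
      validate_proxy_map(proxy_map)
    }
    drop_ids <- character()
    for (id in missing_ids) {
      cand <- proxy_map[proxy_map$MISSING_SNP == id, , drop = FALSE]
      ok <- cand$R2 >= r2_min & cand$PROXY_SNP %in% outcome$SNP &
        !(cand$PROXY_SNP %in% out$SNP)
      if (any(ok)) {
        pick <- which(ok)[1L]
        out$SNP[out$SNP == id] <- cand$PROXY_SNP[pick]
        log <- rbind(log, data.frame(MISSING_SNP = id,
                                     PROXY_SNP = cand$PROXY_SNP[pick],
                                     R2 = cand$R2[pick],
                                     ACTION = "substituted"))
        if (sum(ok) > 1L) {
          alt <- cand$PROXY_SNP[which(ok)[-1L]]
          message("proxy for ", id, ": using ", cand$PROXY_SNP[pick],
                  "; unused alternative(s): ", paste(alt, collapse = ", "))
        }
      } else {
        drop_ids <- c(drop_ids, id)
        log <- rbind(log, data.frame(MISSING_SNP = id, PROXY_SNP = NA,
                                     R2 = NA, ACTION = "dropped"))
      }
    }
    if (length(drop_ids)) {
      message(length(drop_ids), " instrument(s) dropped (no acceptable proxy): ",
              paste(drop_ids, collapse = ", "))
      out <- out[!(out$SNP %in% drop_ids), , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  structure(out, trait_name = attr(exposure, "trait_name"), role = "exposure",
            proxy_log = log, class = c("study_set", "data.frame"))
}
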