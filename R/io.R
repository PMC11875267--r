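#' Read per-sample CpG methylation counts
#'
#' Accepts either one bedGraph-like file per sample with columns
#' `chrom`, `pos` (0-based), `meth`, `total`, or a single wide file with
#' `chrom`, `pos` followed by `meth_<id>`, `total_<id>` column pairs.
#' Sites absent from a per-sample file, or with `total == 0`, are retained
#' as missing cells (zero coverage), never dropped.
#'
#' @param paths one path per sample, or a single wide-format path.
#' @param sample_ids sample identifiers, one per sample.
#' @param autosomes_only drop non-autosomal records (default `TRUE`).
#' @return a [cpg_count_matrix()].
#' @export
read_cpg_counts <- function(paths, sample_ids, autosomes_only = TRUE) {
  if (length(paths) == 1L && length(sample_ids) >= 1L) {
    tab <- read_tsv_checked(paths, n_min_cols = 2L)
    if (ncol(tab) == 4L && length(sample_ids) == 1L) {
      tabs <- list(tab)
    } else {
      if (ncol(tab) != 2L + 2L * length(sample_ids))
        stop("wide counts file must have chrom, pos plus meth/total per sample")
      tabs <- lapply(seq_along(sample_ids), function(j)
        tab[, c(1L, 2L, 2L * j + 1L, 2L * j + 2L)])
    }
  } else {
    if (length(paths) != length(sample_ids))
      stop("need one path per sample id")
    tabs <- lapply(paths, read_tsv_checked, n_min_cols = 4L)
  }
  tabs <- lapply(seq_along(tabs), function(j) {
    t <- tabs[[j]]
    names(t) <- c("chrom", "pos", "meth", "total")
    check_count_cols(t, if (length(paths) == length(tabs)) paths[j] else paths)
    t
  })
  key_all <- unique(do.call(rbind, lapply(tabs, function(t) t[c("chrom", "pos")])))
  key_all <- key_all[order(key_all$chrom, key_all$pos), ]
  key <- paste(key_all$chrom, key_all$pos)
  meth <- total <- matrix(0L, nrow(key_all), length(sample_ids))
  for (j in seq_along(tabs)) {
    i <- match(paste(tabs[[j]]$chrom, tabs[[j]]$pos), key)
    meth[i, j] <- as.integer(tabs[[j]]$meth)
    total[i, j] <- as.integer(tabs[[j]]$total)
  }
  x <- cpg_count_matrix(key_all$chrom, key_all$pos, meth, total, sample_ids)
  if (autosomes_only) x <- filter_autosomes(x, quiet = TRUE)
  x
}

#' Write a CpG count matrix (wide TSV)
#'
#' @param x a `CpGCountMatrix`.
#' @param path output path.
#' @export
write_cpg_counts <- function(x, path) {
  out <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                    check.names = FALSE)
  for (j in seq_along(x$samples)) {
    out[[paste0("meth_", x$samples[j])]] <- x$meth[, j]
    out[[paste0("total_", x$samples[j])]] <- x$total[, j]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, n_min_cols) {
  tab <- tryCatch(read.delim(path, header = looks_headered(path),
                             stringsAsFactors = FALSE),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (ncol(tab) < n_min_cols)
    stop("parse error in ", path, ": expected >= ", n_min_cols, " columns")
  tab
}

looks_headered <- function(path) {
  first <- readLines(path, n = 1L)
  f <- strsplit(first, "\t")[[1]]
  length(f) >= 2L && is.na(suppressWarnings(as.numeric(f[2])))
}

check_count_cols <- function(t, path) {
  bad <- which(!is.finite(suppressWarnings(as.numeric(t$pos))) |
                 !is.finite(suppressWarnings(as.numeric(t$meth))) |
                 !is.finite(suppressWarnings(as.numeric(t$total))))
  if (length(bad))
    stop("parse error in ", path, " at line ", bad[1],
         ": non-numeric pos/meth/total")
  if (any(t$meth > t$total))
    stop("validation error in ", path, " at line ",
         which(t$meth > t$total)[1], ": meth > total")
  invisible(TRUE)
}

#' Read fragment-level methylation records (PAT-like TSV)
#'
#' Rows are `chrom`, first-CpG position, a per-CpG call string over
#' `{C, T}` or `{1, 0}` (`C`/`1` = methylated), and a multiplicity count of
#' identical fragments.
#'
#' @param path input path.
#' @return data.frame of class `fragments` with columns `chrom`, `start`,
#'   `calls` (binary string), `ncpg`, `nmeth`, `mult`.
#' @export
read_fragments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_fragments())
  f <- strsplit(lines, "\t")
  nf <- lengths(f)
  if (any(nf != 4L))
    stop("parse error in ", path, " at line ", which(nf != 4L)[1],
         ": expected 4 tab-separated fields")
  m <- matrix(unlist(f), ncol = 4L, byrow = TRUE)
  calls <- chartr("CT", "10", m[, 3])
  bad <- grepl("[^01]", calls)
  if (any(bad))
    stop("parse error in ", path, " at line ", which(bad)[1],
         ": call characters outside {C,T,0,1}")
  mult <- as.integer(m[, 4])
  if (any(is.na(mult)) || any(mult < 1L))
    stop("validation error in ", path, ": multiplicity must be >= 1")
  fragments(m[, 1], as.integer(m[, 2]), calls, mult)
}

#' Construct a fragment table
#'
#' @param chrom,start fragment location (first CpG, 0-based).
#' @param calls binary call strings ("1" = methylated CpG).
#' @param mult positive integer multiplicities.
#' @export
fragments <- function(chrom, start, calls, mult = 1L) {
  mult <- as.integer(mult)
  if (any(mult < 1L)) stop("multiplicity must be >= 1")
  if (any(!nzchar(calls))) stop("fragments must carry >= 1 CpG call")
  out <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                    calls = as.character(calls),
                    ncpg = nchar(calls),
                    nmeth = nchar(calls) - nchar(gsub("1", "", calls)),
                    mult = mult, stringsAsFactors = FALSE)
  class(out) <- c("fragments", "data.frame")
  out
}

empty_fragments <- function() {
  fragments(character(), integer(), character(), integer())
}

#' Write fragments as PAT-like TSV
#' @param x a `fragments` table.
#' @param path output path.
#' @export
write_fragments <- function(x, path) {
  writeLines(paste(x$chrom, x$start, x$calls, x$mult, sep = "\t"), path)
  invisible(path)
}

#' Read / write BED3 interval files
#'
#' BED coordinates are natively 0-based half-open, matching the package
#' convention.
#'
#' @param path file path.
#' @return `genomic_intervals`.
#' @export
read_bed <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gi <- genomic_intervals(tab[[1]], tab[[2]], tab[[3]])
  if (ncol(tab) >= 4L) gi$name <- as.character(tab[[4]])
  gi
}

#' @rdname read_bed
#' @param x interval table (optionally with a `name` column).
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end", intersect("name", names(x)))
  write.table(as.data.frame(x)[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the cohort sample table
#'
#' Headered TSV with columns `sample_id`, `patient_id`, `group`
#' (Control / A-RRMS / S-RRMS / PMS), `age`, `sex`, `race`,
#' `disease_duration`, `dmt_type`, `dmt_effectiveness`,
#' `followup_duration`, `baseline_pdds`.
#'
#' @param path file path.
#' @export
read_sample_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validate_sample_table(tab)
}

validate_sample_table <- function(tab) {
  groups <- c("Control", "A-RRMS", "S-RRMS", "PMS")
  if (!all(tab$group %in% groups))
    stop("group labels must be one of: ", paste(groups, collapse = ", "))
  if (any(tab$age <= 0)) stop("ages must be positive")
  if (anyDuplicated(tab$sample_id)) stop("one row per sample required")
  tab
}

#' Write the cohort sample table
#' @param tab sample table.
#' @param path output path.
#' @export
write_sample_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read longitudinal outcome series (patient, day, PDDS)
#'
#' @param path headered TSV with columns `patient_id`, `day`, `pdds`.
#' @return data.frame sorted by patient and day; days must be strictly
#'   increasing within a patient and PDDS in 0..8.
#' @export
read_outcomes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validate_outcomes(tab)
}

validate_outcomes <- function(tab) {
  if (any(tab$pdds < 0 | tab$pdds > 8)) stop("PDDS must lie in 0..8")
  if (any(tab$day < 0)) stop("days must be >= 0")
  tab <- tab[order(tab$patient_id, tab$day), ]
  dup <- unlist(tapply(tab$day, tab$patient_id, function(d) c(FALSE, diff(d) <= 0)))
  if (any(dup)) stop("days must be strictly increasing within a patient")
  rownames(tab) <- NULL
  tab
}

#' @rdname read_outcomes
#' @param tab outcome table.
#' @export
write_outcomes <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a participant-profile table and count extreme-disability samples
#'
#' The participant profile records, per cohort group, the number of samples
#' in each PDDS stratum. The extreme-disability restriction keeps samples
#' with PDDS <= 1 (normal/mild) or PDDS >= 6 (most severe), the two ends of
#' the patient-reported ambulatory disability scale used for the
#' severity classifiers.
#'
#' @param path headered TSV with a `stratum` column and one count column per
#'   cohort group. Defaults to the packaged cfDNA MS cohort profile.
#' @return list with `n_le1`, `n_ge6`, and `n_extreme` (their sum).
#' @export
count_extreme_disability <- function(path = system.file("extdata",
                                                        "participant_profile.tsv",
                                                        package = "cfmethms")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  counts <- function(stratum) {
    row <- tab[tab$stratum == stratum, -1, drop = FALSE]
    if (nrow(row) != 1L) stop("profile must contain one '", stratum, "' row")
    sum(as.integer(row))
  }
  n_le1 <- counts("pdds_le1")
  n_ge6 <- counts("pdds_ge6")
  list(n_le1 = n_le1, n_ge6 = n_ge6, n_extreme = n_le1 + n_ge6)
}
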