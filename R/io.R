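# File formats: cohort CSV/TSV, IGV SEG, binned TSV, calls TSV, arm BED.
#
# Readers validate rather than coerce: every rejection names the file, the
# row, and the offending field.  On-disk coordinates follow the format's own
# convention (SEG 1-based inclusive, BED/binned TSV 0-based half-open);
# in-memory containers are GRanges (1-based closed).

.readTable <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.seg$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.requireColumns <- function(d, cols, path) {
  miss <- setdiff(cols, names(d))
  if (length(miss)) {
    mbStop(sprintf("%s: missing mandatory column(s): %s", path,
                   paste(miss, collapse = ", ")))
  }
}

.cohortColumns <- c("patient_id", "age_years", "m_stage", "resection",
                    "histology", "therapy", "rt_start_years", "pfs_years",
                    "os_years", "pfs_event", "os_event")

#' Read a clinical cohort table
#'
#' CSV or TSV (by extension) with the documented schema: \code{patient_id},
#' \code{age_years}, \code{m_stage} (M0/M+), \code{resection} (R0/R+),
#' \code{histology} (CMB/DMB/LCA), \code{therapy}
#' (infant_type/primary_CSI), \code{rt_start_years} (empty = none),
#' \code{pfs_years}, \code{os_years}, \code{pfs_event}, \code{os_event}.
#' Every malformed value is rejected with its row number and field.
#'
#' @param path file path
#' @return validated data.frame of patient records
#' @export
readCohort <- function(path) {
  d <- .readTable(path)
  .requireColumns(d, .cohortColumns, path)
  probs <- character()
  bad <- function(rows, field, why) {
    if (any(rows)) sprintf("%s: row(s) %s: field '%s' %s", basename(path),
                           paste(which(rows), collapse = ","), field, why)
  }
  num <- function(col) suppressWarnings(as.numeric(d[[col]]))
  lgl <- function(col) {
    v <- d[[col]]
    if (is.logical(v)) return(v)
    out <- rep(NA, length(v))
    out[v %in% c("TRUE", "true", "1", 1)] <- TRUE
    out[v %in% c("FALSE", "false", "0", 0)] <- FALSE
    out
  }
  d$age_years <- num("age_years")
  d$rt_start_years <- num("rt_start_years")
  d$pfs_years <- num("pfs_years")
  d$os_years <- num("os_years")
  d$pfs_event <- lgl("pfs_event")
  d$os_event <- lgl("os_event")
  probs <- c(probs,
    bad(is.na(d$age_years) | d$age_years < 0, "age_years", "must be a non-negative number"),
    bad(!d$m_stage %in% c("M0", "M+"), "m_stage", "must be M0 or M+"),
    bad(!d$resection %in% c("R0", "R+"), "resection", "must be R0 or R+"),
    bad(!d$histology %in% c("CMB", "DMB", "LCA"), "histology", "must be CMB, DMB or LCA"),
    bad(!d$therapy %in% c("infant_type", "primary_CSI"), "therapy",
        "must be infant_type or primary_CSI"),
    bad(!is.na(d$rt_start_years) & d$rt_start_years < 0, "rt_start_years",
        "must be >= 0 when present"),
    bad(is.na(d$pfs_years) | d$pfs_years <= 0, "pfs_years", "must be a positive number"),
    bad(is.na(d$os_years) | d$os_years <= 0, "os_years", "must be a positive number"),
    bad(is.na(d$pfs_event), "pfs_event", "must be TRUE/FALSE"),
    bad(is.na(d$os_event), "os_event", "must be TRUE/FALSE"))
  ok <- !is.na(d$pfs_years) & !is.na(d$os_years)
  probs <- c(probs, bad(ok & d$os_years < d$pfs_years, "os_years",
                        "must be >= pfs_years"))
  probs <- Filter(Negate(is.null), probs)
  if (length(probs)) mbStop(paste(probs, collapse = "\n"))
  if (anyDuplicated(d$patient_id)) mbStop(sprintf("%s: duplicated patient_id", path))
  d[, .cohortColumns]
}

#' Write a clinical cohort table
#' @param patients cohort data.frame
#' @param path output path (.csv or .tsv)
#' @export
writeCohort <- function(patients, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(patients[, .cohortColumns], path, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read molecular label table
#'
#' CSV/TSV with \code{patient_id}, \code{group}, \code{subgroup} and the
#' classifier scores \code{mcf_score}, \code{group_score},
#' \code{subgroup_score}.
#'
#' @param path file path
#' @return data.frame
#' @export
readLabels <- function(path) {
  d <- .readTable(path)
  .requireColumns(d, c("patient_id", "group", "subgroup", "mcf_score",
                       "group_score", "subgroup_score"), path)
  badg <- !d$group %in% c("Group3", "Group4")
  bads <- !d$subgroup %in% .SUBGROUPS
  if (any(badg)) mbStop(sprintf("%s: row(s) %s: field 'group' must be Group3/Group4",
                                basename(path), paste(which(badg), collapse = ",")))
  if (any(bads)) mbStop(sprintf("%s: row(s) %s: field 'subgroup' must be I..VIII",
                                basename(path), paste(which(bads), collapse = ",")))
  d
}

#' Write molecular label table
#' @param labels label data.frame
#' @param path output path
#' @export
writeLabels <- function(labels, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(labels, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IGV SEG file into copy-number profiles
#'
#' Expects the de-facto columns \code{ID}, \code{chrom}, \code{loc.start},
#' \code{loc.end}, \code{seg.mean} (\code{num.mark} optional).  SEG
#' coordinates are 1-based inclusive and map directly onto GRanges.
#' Segments are sorted; overlapping segments within a sample are a data
#' error.  Chromosomes absent from the genome model are skipped with a
#' warning, or rejected when \code{strict = TRUE}.
#'
#' @param path SEG file path
#' @param genome a \linkS4class{GenomeModel} used to validate chromosomes
#' @param strict error (instead of warn+skip) on unknown chromosomes
#' @return named list of \linkS4class{CNProfile}s
#' @export
readSeg <- function(path, genome = hg19ArmModel(), strict = FALSE) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  names(d) <- tolower(names(d))
  .requireColumns(d, c("id", "chrom", "loc.start", "loc.end", "seg.mean"), path)
  d$chrom <- ifelse(grepl("^chr", d$chrom), d$chrom, paste0("chr", d$chrom))
  known <- unique(as.character(seqnames(arms(genome))))
  unk <- !d$chrom %in% known
  if (any(unk)) {
    msg <- sprintf("%s: row(s) %s: unknown chromosome", basename(path),
                   paste(which(unk), collapse = ","))
    if (strict) mbStop(msg)
    warning(msg, "; skipped")
    d <- d[!unk, , drop = FALSE]
  }
  lapply(split(d, d$id), function(s) {
    gr <- GRanges(s$chrom, IRanges(start = s$`loc.start`, end = s$`loc.end`),
                  log2 = s$`seg.mean`)
    gr <- sort(gr)
    sp <- split(gr, as.character(seqnames(gr)))
    for (chr in names(sp)) {
      g <- sp[[chr]]
      if (length(g) > 1L && any(start(g)[-1L] <= end(g)[-length(g)])) {
        mbStop(sprintf("%s: sample %s: overlapping segments on %s",
                       basename(path), s$id[1], chr))
      }
    }
    CNProfile(s$id[1], gr, provenance = "segmented")
  })
}

#' Write profiles as an IGV SEG file
#' @param profiles list of \linkS4class{CNProfile}s (or a single profile)
#' @param path output path
#' @export
writeSeg <- function(profiles, path) {
  if (methods::is(profiles, "CNProfile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    b <- profileBins(p)
    data.frame(ID = sampleId(p), chrom = as.character(seqnames(b)),
               loc.start = start(b), loc.end = end(b),
               num.mark = pmax(1L, round(width(b) / 1e4)),
               seg.mean = b$log2)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binned log2-ratio TSV (0-based half-open coordinates)
#'
#' Columns \code{chrom}, \code{start}, \code{end}, \code{log2}, optional
#' \code{sample_id}; \code{start} is 0-based, \code{end} exclusive, converted
#' to GRanges on read.
#'
#' @param path file path
#' @param sample_id sample name used when the file has no sample column
#' @return a \linkS4class{CNProfile} (or named list when multi-sample)
#' @export
readBinnedTsv <- function(path, sample_id = tools::file_path_sans_ext(basename(path))) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  .requireColumns(d, c("chrom", "start", "end", "log2"), path)
  bad <- d$end <= d$start
  if (any(bad)) mbStop(sprintf("%s: row(s) %s: field 'end' must exceed 'start'",
                               basename(path), paste(which(bad), collapse = ",")))
  mk <- function(s, id) CNProfile(id, GRanges(s$chrom,
    IRanges(start = s$start + 1L, end = s$end), log2 = s$log2))
  if ("sample_id" %in% names(d)) {
    lapply(split(d, d$sample_id), function(s) mk(s, s$sample_id[1]))
  } else {
    mk(d, sample_id)
  }
}

#' Write a profile as a binned TSV (0-based half-open)
#' @param profile a \linkS4class{CNProfile}
#' @param path output path
#' @export
writeBinnedTsv <- function(profile, path) {
  b <- profileBins(profile)
  utils::write.table(
    data.frame(chrom = as.character(seqnames(b)), start = start(b) - 1L,
               end = end(b), log2 = b$log2),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-sample molecular calls as TSV
#' @param calls data.frame from \code{\link{callCohort}}
#' @param path output path
#' @export
writeCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-sample molecular calls written by \code{\link{writeCalls}}
#' @param path file path
#' @return data.frame
#' @export
readCalls <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  .requireColumns(d, c("sample_id", "chr7_gain", "chr8_loss", "chr11_loss",
                       "wca_phenotype", "myc_amp", "mycn_amp"), path)
  d
}

#' Write genome arms (and loci) as BED
#'
#' BED is 0-based half-open; arm rows are named by arm id, locus rows by
#' locus name.
#'
#' @param genome a \linkS4class{GenomeModel}
#' @param path output path
#' @export
writeGenomeBed <- function(genome, path) {
  a <- arms(genome); lc <- loci(genome)
  rows <- data.frame(chrom = c(as.character(seqnames(a)), as.character(seqnames(lc))),
                     start = c(start(a), start(lc)) - 1L,
                     end = c(end(a), end(lc)),
                     name = c(paste0("arm:", a$arm),
                              if (length(lc)) paste0("locus:", names(lc)) else character()))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genome model from a BED written by \code{\link{writeGenomeBed}}
#' @param path BED path
#' @param genome_name build label for the returned model
#' @return a \linkS4class{GenomeModel}
#' @export
readGenomeBed <- function(path, genome_name = "custom") {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "name"))
  isArm <- grepl("^arm:", d$name)
  a <- d[isArm, ]; l <- d[!isArm, ]
  armsGr <- GRanges(a$chrom, IRanges(start = a$start + 1L, end = a$end),
                    arm = sub("^arm:", "", a$name))
  armsGr$acrocentric <- armsGr$arm %in% .hg19_acro
  lociGr <- GRanges(l$chrom, IRanges(start = l$start + 1L, end = l$end))
  names(lociGr) <- sub("^locus:", "", l$name)
  GenomeModel(armsGr, lociGr, genome = genome_name)
}
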