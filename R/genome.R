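#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps pintersect mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata metadata<-
NULL

#' Genome model: chromosome arms and named loci
#'
#' Holds the arm intervals (p before q, centromere excluded) used for
#' arm-level copy-number calling, and the named loci (\code{MYC}, \code{MYCN})
#' used for amplification calling.  Arms are \code{GRanges} with metadata
#' columns \code{arm} (e.g. \code{"7q"}) and \code{acrocentric}; loci are a
#' named \code{GRanges}.
#'
#' @slot arms GRanges of arm intervals with mcols \code{arm}, \code{acrocentric}.
#' @slot loci named GRanges of amplification loci.
#' @slot genome build tag, e.g. \code{"hg19"}.
#' @export
setClass("GenomeModel",
  representation(arms = "GRanges", loci = "GRanges", genome = "character"))

setValidity("GenomeModel", function(object) {
  a <- object@arms
  msgs <- character()
  if (is.null(a$arm) || anyDuplicated(a$arm)) {
    msgs <- c(msgs, "arms must carry unique 'arm' names")
  }
  # arms within a chromosome must be disjoint, p before q
  for (chr in unique(as.character(seqnames(a)))) {
    ai <- a[seqnames(a) == chr]
    if (length(ai) == 2L) {
      p <- ai[grepl("p$", ai$arm)]; q <- ai[grepl("q$", ai$arm)]
      if (length(p) == 1L && length(q) == 1L && end(p) >= start(q)) {
        msgs <- c(msgs, sprintf("arms of %s overlap or q precedes p", chr))
      }
    }
  }
  if (length(object@loci) > 0) {
    hits <- findOverlaps(object@loci, a, type = "within")
    if (length(unique(queryHits(hits))) != length(object@loci)) {
      msgs <- c(msgs, "every locus must lie inside exactly one arm")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a genome model
#'
#' @param arms GRanges with mcols \code{arm} (character, e.g. "1p") and
#'   optionally \code{acrocentric} (logical; defaults to FALSE).
#' @param loci named GRanges of amplification loci (may be empty).
#' @param genome build label.
#' @return a \linkS4class{GenomeModel}.
#' @export
GenomeModel <- function(arms, loci = GRanges(), genome = "custom") {
  if (is.null(arms$acrocentric)) arms$acrocentric <- rep(FALSE, length(arms))
  new("GenomeModel", arms = arms, loci = loci, genome = genome)
}

#' @export
setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel (%s): %d arms on %d chromosomes, %d loci (%s)\n",
    object@genome, length(object@arms),
    length(unique(as.character(seqnames(object@arms)))),
    length(object@loci), paste(names(object@loci), collapse = ", ")))
})

#' Arm intervals of a genome model
#' @param x a GenomeModel
#' @return GRanges of arms
#' @export
arms <- function(x) x@arms

#' Named amplification loci of a genome model
#' @param x a GenomeModel
#' @return named GRanges
#' @export
loci <- function(x) x@loci

#' Arm identifiers
#' @param x a GenomeModel
#' @return character vector such as \code{c("1p","1q",...)}
#' @export
armNames <- function(x) as.character(x@arms$arm)

# hg19 autosome lengths and centromere bounds (UCSC gap table).
.hg19 <- data.frame(
  chrom = paste0("chr", 1:22),
  len = c(249250621L, 243199373L, 198022430L, 191154276L, 180915260L,
          171115067L, 159138663L, 146364022L, 141213431L, 135534747L,
          135006516L, 133851895L, 115169878L, 107349540L, 102531392L,
          90354753L,  81195210L,  78077248L,  59128983L,  63025520L,
          48129895L,  51304566L),
  cen_start = c(121535434L, 92326171L, 90504854L, 49660117L, 46405641L,
                58830166L, 58054331L, 43838887L, 47367679L, 39254935L,
                51644205L, 34856694L, 16000000L, 16000000L, 17000000L,
                35335801L, 22263006L, 15460898L, 24681782L, 26369569L,
                11288129L, 13000000L),
  cen_end = c(124535434L, 95326171L, 93504854L, 52660117L, 49405641L,
              61830166L, 61054331L, 46838887L, 50367679L, 42254935L,
              54644205L, 37856694L, 19000000L, 19000000L, 20000000L,
              38335801L, 25263006L, 18460898L, 27681782L, 29369569L,
              14288129L, 16000000L),
  stringsAsFactors = FALSE
)

.hg19_acro <- paste0(c(13, 14, 15, 21, 22), "p")

#' hg19 arm model with MYC and MYCN loci
#'
#' Autosomal p/q arm intervals derived from the UCSC hg19 cytoband/gap table
#' (centromeres excluded), with the \emph{MYC} (8q24) and \emph{MYCN} (2p24)
#' loci.  Sex chromosomes are omitted: baselines and arm calls are autosomal.
#'
#' @return a \linkS4class{GenomeModel}
#' @export
hg19ArmModel <- function() {
  h <- .hg19
  arms <- GRanges(
    seqnames = rep(h$chrom, each = 2L),
    ranges = IRanges(
      start = as.vector(rbind(1L, h$cen_end + 1L)),
      end = as.vector(rbind(h$cen_start, h$len))),
    arm = paste0(rep(sub("chr", "", h$chrom), each = 2L), c("p", "q")))
  arms$acrocentric <- arms$arm %in% .hg19_acro
  lc <- GRanges(c("chr8", "chr2"),
                IRanges(start = c(128747680L, 16080683L),
                        end = c(128753674L, 16087129L)))
  names(lc) <- c("MYC", "MYCN")
  GenomeModel(arms = arms, loci = lc, genome = "hg19")
}

#' Tile the arms of a genome model into fixed-width bins
#'
#' Bins tile each arm independently at \code{bin_size} bp; the final bin of an
#' arm may be shorter.  Bins never straddle a centromere.
#'
#' @param genome a \linkS4class{GenomeModel}
#' @param bin_size bin width in bp
#' @return GRanges of bins with mcol \code{arm}
#' @export
binGenome <- function(genome, bin_size = 1e6) {
  stopifnot(is.numeric(bin_size), bin_size >= 1)
  a <- arms(genome)
  starts <- lapply(seq_along(a), function(i) seq(start(a)[i], end(a)[i], by = bin_size))
  nper <- lengths(starts)
  s <- unlist(starts)
  out <- GRanges(rep(as.character(seqnames(a)), nper),
                 IRanges(s, pmin(s + bin_size - 1, rep(end(a), nper))),
                 arm = rep(a$arm, nper))
  metadata(out)$bin_size <- bin_size
  out
}
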