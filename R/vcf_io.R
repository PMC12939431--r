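#' Write an isolate call set as VCF
#'
#' Emits a VCF 4.2 file with `GT`, `AD`, `DP` and `AF` genotype fields for
#' one sample. Records are sorted by chromosome (layout order when supplied,
#' else order of first appearance) and position on write.
#'
#' @param calls an `IsolateCallSet` (or any list with `id` and a `variants`
#'   data.frame holding `chrom`, `pos`, `ref`, `alt`, `genotype`, `af`,
#'   `depth`).
#' @param path output file.
#' @param layout optional [genome_layout()] used for `##contig` headers and
#'   chromosome ordering.
#' @return `path`, invisibly.
#' @export
write_isolate_vcf <- function(calls, path, layout = NULL) {
  v <- calls$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##source=malines",
           if (!is.null(layout))
             sprintf("##contig=<ID=%s,length=%d>", layout$chrom,
                     layout$length),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alt allele fraction\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", calls$id, sep = "\t"))
  if (!is.null(v) && nrow(v)) {
    chrom_order <- if (!is.null(layout)) layout$chrom else unique(v$chrom)
    v <- v[order(match(v$chrom, chrom_order), v$pos), ]
    gt <- c(het = "0/1", `hom-alt` = "1/1", homalt = "1/1",
            `hom-ref` = "0/0", homref = "0/0")[v$genotype]
    gt[is.na(gt)] <- "0/1"
    dp <- as.integer(round(v$depth))
    ad_alt <- as.integer(round(v$af * dp))
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                  "GT:AD:DP:AF",
                  sprintf("%s:%d,%d:%d:%.10g", gt, dp - ad_alt, ad_alt, dp,
                          v$af),
                  sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an isolate call set from VCF
#'
#' Parses a single-sample VCF (via \pkg{vcfR}) back into the variant-record
#' data.frame used throughout the package. The allele fraction is taken from
#' the `AF` genotype field when present, else recomputed as AD alt / DP.
#'
#' @param path VCF file.
#' @return list of class `IsolateCallSet` with elements `id` and `variants`
#'   (no marker genotypes or depth track; those travel in separate files).
#' @export
read_isolate_vcf <- function(path) {
  vr <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vr@fix, stringsAsFactors = FALSE)
  id <- if (ncol(vr@gt) >= 2) colnames(vr@gt)[2] else "sample"
  if (!nrow(fix)) {
    v <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), genotype = character(),
                    af = numeric(), depth = numeric(),
                    stringsAsFactors = FALSE)
  } else {
    gt <- vcfR::extract.gt(vr, element = "GT")[, 1]
    dp <- as.numeric(vcfR::extract.gt(vr, element = "DP")[, 1])
    af <- suppressWarnings(as.numeric(vcfR::extract.gt(vr, element = "AF")[, 1]))
    if (all(is.na(af))) {
      ad <- vcfR::extract.gt(vr, element = "AD")[, 1]
      alt_ad <- as.numeric(vapply(strsplit(ad, ","), `[`, "", 2))
      af <- alt_ad / dp
    }
    geno <- rep("het", nrow(fix))
    geno[gt %in% c("1/1", "1|1")] <- "hom-alt"
    geno[gt %in% c("0/0", "0|0")] <- "hom-ref"
    v <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, genotype = geno,
                    af = af, depth = dp, stringsAsFactors = FALSE)
  }
  out <- list(id = id, variants = v)
  class(out) <- "IsolateCallSet"
  out
}

#' Write marker genotypes as TSV
#' @param markers a [build_marker_map()] result.
#' @param genotypes character vector aligned to `markers` rows (`het`,
#'   `homA`, `homB`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_marker_genotypes <- function(markers, genotypes, path) {
  stopifnot(length(genotypes) == nrow(markers))
  utils::write.table(data.frame(chrom = markers$chrom, pos = markers$pos,
                                genotype = genotypes),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read marker genotypes from TSV
#' @param path file written by [write_marker_genotypes()].
#' @return data.frame with `chrom`, `pos`, `genotype`.
#' @export
read_marker_genotypes <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a depth track as bedGraph
#' @param depth data.frame with `chrom`, `start`, `end`, `ratio` (0-based
#'   half-open windows, normalized depth).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_depth_bedgraph <- function(depth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph name=depth_ratio", con)
  writeLines(sprintf("%s\t%d\t%d\t%.10g", depth$chrom,
                     as.integer(depth$start), as.integer(depth$end),
                     depth$ratio), con)
  invisible(path)
}

#' Read a depth track from bedGraph
#' @param path file with columns chrom, start, end, value (track lines are
#'   skipped).
#' @return data.frame with `chrom`, `start`, `end`, `ratio`.
#' @export
read_depth_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines)]
  d <- utils::read.table(text = lines, sep = "\t",
                         col.names = c("chrom", "start", "end", "ratio"),
                         stringsAsFactors = FALSE)
  d
}
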