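# Readers and writers for the standard formats the pipeline touches.
#
# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# Conversion to/from 1-based inclusive happens only at the GTF and VCF
# boundaries, which are 1-based on disk. BED and SAM POS are handled at the
# parser edge as well (SAM POS is 1-based; BED is already 0-based half-open).

#' Read a FASTA file into a named character vector
#'
#' Sequence names are taken up to the first whitespace and sequences are
#' upper-cased. Duplicate names are a format error.
#'
#' @param path path to a FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stopf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  if (length(x) == 0L) stopf("empty FASTA: %s", path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) stopf("duplicate sequence names in FASTA: %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  setNames(toupper(as.character(x)), nm)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read FASTQ records
#'
#' @param path path to an (optionally gzipped) FASTQ file.
#' @return data.frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(methods::slot(x, "quality")),
             stringsAsFactors = FALSE)
}

#' Write FASTQ records
#'
#' @param reads data.frame with columns `read_id`, `seq`, `qual`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- rbind(paste0("@", reads$read_id), reads$seq, "+", reads$qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

# ---- gene models -----------------------------------------------------------

new_gene_model <- function(gene_id, biotype, chrom, start, end, strand,
                           transcripts, cds = NULL) {
  stopifnot(start >= 0, start < end, strand %in% c("+", "-", "."))
  for (tx in transcripts) {
    if (any(tx$start < start) || any(tx$end > end))
      stopf("gene %s: exon outside gene span", gene_id)
    o <- order(tx$start)
    if (any(tx$end[o][-nrow(tx)] > tx$start[o][-1]))
      stopf("gene %s: overlapping exons within a transcript", gene_id)
  }
  structure(list(gene_id = gene_id, biotype = biotype, chrom = chrom,
                 start = start, end = end, strand = strand,
                 transcripts = transcripts, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d(%s), %d transcript(s)\n",
              x$gene_id, x$biotype, x$chrom, x$start, x$end, x$strand,
              length(x$transcripts)))
  invisible(x)
}

## exons of the (first) transcript, sorted by genomic start, 0-based half-open
gene_exons <- function(gene, tx = 1L) {
  ex <- gene$transcripts[[tx]]
  ex[order(ex$start), , drop = FALSE]
}

## introns between the sorted exons; zero-row data.frame when single-exon
gene_introns <- function(gene, tx = 1L) {
  ex <- gene_exons(gene, tx)
  if (nrow(ex) < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
}

#' Read gene models from a GTF file
#'
#' Parses gene/transcript/exon (and optional CDS) features, converts the
#' 1-based inclusive GTF coordinates to the internal 0-based half-open
#' convention, groups exons per transcript sorted by start, and keeps the
#' `gene_biotype` attribute.
#'
#' @param path path to a GTF file.
#' @return named list of gene models.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  if (!any(type == "exon")) stopf("GTF '%s' contains no exon features", path)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  gid <- as.character(md$gene_id)
  tid <- if ("transcript_id" %in% names(md)) as.character(md$transcript_id) else gid
  biotype <- if ("gene_biotype" %in% names(md)) as.character(md$gene_biotype) else
    rep("protein_coding", length(gr))

  genes <- list()
  gi <- which(type == "gene")
  if (length(gi) == 0L) gi <- which(!duplicated(gid))  # infer spans below
  for (i in gi) {
    g <- gid[i]
    rows <- which(gid == g)
    ex <- rows[type[rows] == "exon"]
    gspan <- if (type[i] == "gene") c(start0[i], end0[i]) else
      c(min(start0[ex]), max(end0[ex]))
    txs <- split(ex, tid[ex])
    transcripts <- lapply(txs, function(r)
      data.frame(start = sort(start0[r]), end = end0[r][order(start0[r])]))
    cds_rows <- rows[type[rows] == "CDS"]
    cds <- if (length(cds_rows)) c(min(start0[cds_rows]), max(end0[cds_rows])) else NULL
    bt <- biotype[i]
    if (is.na(bt)) bt <- "protein_coding"
    genes[[g]] <- new_gene_model(g, bt, chrom[i], gspan[1], gspan[2],
                                 strand[i], transcripts, cds)
  }
  genes
}

#' Write gene models to GTF
#'
#' @param genes list of gene models (see [read_gtf()]).
#' @param path output path.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  fmt <- function(chrom, feat, s0, e0, strand, attr)
    sprintf("%s\tcircedit\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, feat, s0 + 1L, e0, strand, attr)
  for (g in genes) {
    ga <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id, g$biotype)
    lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand, ga))
    for (tx_id in names(g$transcripts)) {
      ta <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                    g$gene_id, tx_id, g$biotype)
      ex <- g$transcripts[[tx_id]]
      lines <- c(lines, fmt(g$chrom, "transcript", min(ex$start), max(ex$end), g$strand, ta))
      for (k in seq_len(nrow(ex)))
        lines <- c(lines, fmt(g$chrom, "exon", ex$start[k], ex$end[k], g$strand, ta))
      if (!is.null(g$cds)) {
        for (k in seq_len(nrow(ex))) {
          cs <- max(ex$start[k], g$cds[1]); ce <- min(ex$end[k], g$cds[2])
          if (cs < ce) lines <- c(lines, fmt(g$chrom, "CDS", cs, ce, g$strand, ta))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- repeats (BED6) --------------------------------------------------------

#' Read a RepeatMasker-style BED6 file of repeat elements
#'
#' The name column is the repeat family (e.g. "AluSx3"); elements whose family
#' begins with "Alu" are flagged `is_alu`.
#'
#' @param path path to a BED6 file (0-based half-open on disk).
#' @return data.frame with columns chrom, start, end, family, score, strand,
#'   is_alu.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  raw <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", fill = FALSE)
  if (ncol(raw) < 6L)
    stopf("BED '%s' has %d columns; 6 required (strand missing)", path, ncol(raw))
  df <- data.frame(chrom = raw[[1]], start = as.integer(raw[[2]]),
                   end = as.integer(raw[[3]]), family = raw[[4]],
                   score = as.numeric(raw[[5]]), strand = raw[[6]],
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stopf("BED '%s': start >= end", path)
  if (!all(df$strand %in% c("+", "-", ".")))
    stopf("BED '%s': invalid strand symbol", path)
  df$is_alu <- startsWith(df$family, "Alu")
  df
}

#' Write repeat elements (or any interval table) as BED6
#'
#' @param df data.frame with chrom, start, end, family (or name), score, strand.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  name <- if ("family" %in% names(df)) df$family else df$name
  out <- data.frame(df$chrom, df$start, df$end, name,
                    if ("score" %in% names(df)) df$score else 0, df$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---- VCF -------------------------------------------------------------------

#' Read biallelic SNVs from a VCF file
#'
#' @param path path to a VCF 4.x file.
#' @return data.frame with chrom, pos (0-based), ref, alt, source_tag.
#' @export
read_vcf_sites <- function(path) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  df <- data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]) - 1L,
                   ref = toupper(fx[, "REF"]), alt = toupper(fx[, "ALT"]),
                   stringsAsFactors = FALSE)
  df <- df[nchar(df$ref) == 1L & nchar(df$alt) == 1L &
             df$ref %in% DNA_BASES & df$alt %in% DNA_BASES, , drop = FALSE]
  if (any(df$ref == df$alt)) stopf("VCF '%s': REF equals ALT", path)
  df$source_tag <- "known_vcf"
  rownames(df) <- NULL
  df
}

#' Write SNVs as a minimal VCF 4.2 file
#'
#' @param snps data.frame with chrom, pos (0-based), ref, alt.
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths.
#' @export
write_vcf <- function(snps, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snps)) sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                                  snps$chrom, snps$pos + 1L, snps$ref, snps$alt)
          else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- SAM -------------------------------------------------------------------

parse_cigar <- function(cigar) {
  if (cigar == "*") return(data.frame(op = character(0), len = integer(0)))
  ops <- str_chars(gsub("[0-9]+", "", cigar))
  lens <- as.integer(strsplit(cigar, "[MIDNSHP=X]")[[1]])
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

cigar_ref_len <- function(cigar) {
  if (cigar == "*") return(0L)
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
}

#' Read aligned reads from a SAM file
#'
#' Unmapped reads (flag 0x4) are returned with `is_linear_mapped = FALSE` and
#' `NA` coordinates. Reference names must be declared in the header.
#'
#' @param path path to a SAM file with header.
#' @return data.frame with read_id, flag, chrom, pos (0-based start), mapq,
#'   cigar, seq, qual, is_linear_mapped, end (0-based exclusive).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stopf("SAM file not found: %s", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  refs <- sub(".*SN:([^\t]+).*", "\\1", sq)
  if (length(body) == 0L)
    return(data.frame(read_id = character(0), flag = integer(0),
                      chrom = character(0), pos = integer(0), mapq = integer(0),
                      cigar = character(0), seq = character(0),
                      qual = character(0), is_linear_mapped = logical(0),
                      end = integer(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(get(2))
  chrom <- get(3)
  unmapped <- bitwAnd(flag, 4L) != 0L
  bad <- !unmapped & !(chrom %in% refs)
  if (any(bad))
    stopf("SAM '%s': reference '%s' absent from header", path, chrom[bad][1])
  cigar <- get(6)
  pos <- as.integer(get(4)) - 1L
  pos[unmapped] <- NA_integer_
  chrom[unmapped] <- NA_character_
  reflen <- vapply(cigar, cigar_ref_len, 0L, USE.NAMES = FALSE)
  df <- data.frame(read_id = get(1), flag = flag, chrom = chrom, pos = pos,
                   mapq = as.integer(get(5)), cigar = cigar,
                   seq = toupper(get(10)), qual = get(11),
                   is_linear_mapped = !unmapped,
                   end = pos + reflen, stringsAsFactors = FALSE)
  nq <- nchar(df$seq) != nchar(df$qual) & df$qual != "*"
  if (any(nq)) stopf("SAM '%s': SEQ/QUAL length mismatch for %s", path,
                     df$read_id[nq][1])
  df
}

#' Write aligned reads as SAM
#'
#' @param reads data.frame as returned by [read_alignments()].
#' @param contigs named integer vector of contig lengths for the header.
#' @param path output path.
#' @export
write_sam <- function(reads, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  body <- if (nrow(reads))
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            reads$read_id, reads$flag,
            ifelse(reads$is_linear_mapped, reads$chrom, "*"),
            ifelse(reads$is_linear_mapped, reads$pos + 1L, 0L),
            reads$mapq, reads$cigar, reads$seq, reads$qual)
  else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- editing summary BED ---------------------------------------------------

#' Write per-gene/segment editing summaries as BED6+2
#'
#' One row per (gene, segment) that carries at least one editing site. The
#' name is "gene|segment", the score the number of editing sites, and two
#' extra columns give the summed segment length and the mean editing ratio.
#'
#' @param summaries data.frame from [summarize_segments()].
#' @param path output path.
#' @export
write_editing_bed <- function(summaries, path) {
  s <- summaries[summaries$n_sites >= 1L, , drop = FALSE]
  out <- data.frame(s$chrom, s$start, s$end,
                    paste0(s$gene_id, "|", s$segment), s$n_sites, s$strand,
                    s$segment_length, round(s$mean_editing_ratio, 6))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read back an editing summary BED6+2 file
#'
#' @param path path written by [write_editing_bed()].
#' @return data.frame mirroring the written records.
#' @export
read_editing_bed <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 8L) stopf("editing BED '%s' must have 8 columns", path)
  parts <- strsplit(raw[[4]], "|", fixed = TRUE)
  data.frame(chrom = raw[[1]], start = as.integer(raw[[2]]),
             end = as.integer(raw[[3]]),
             gene_id = vapply(parts, `[[`, "", 1),
             segment = vapply(parts, `[[`, "", 2),
             n_sites = as.integer(raw[[5]]), strand = raw[[6]],
             segment_length = as.integer(raw[[7]]),
             mean_editing_ratio = as.numeric(raw[[8]]),
             stringsAsFactors = FALSE)
}
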