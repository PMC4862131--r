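#' Read a FASTA reference
#'
#' Thin wrapper over Biostrings that returns upper-cased plain character
#' sequences keyed by the first whitespace-delimited token of each header.
#' IUPAC ambiguity codes are preserved; their presence is flagged via the
#' `has_ambiguity` attribute and a warning.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  info <- file.info(path)
  if (is.na(info$size)) stop("no such file: ", path)
  if (info$size == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  dna <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA (", path, "): ",
                             conditionMessage(e))
  )
  out <- toupper(as.character(dna))
  names(out) <- sub("\\s.*$", "", names(dna))
  amb <- grepl("[^ACGT]", out)
  if (any(amb)) {
    warning("ambiguity codes present in sequence(s): ",
            paste(names(out)[amb], collapse = ", "))
    attr(out, "has_ambiguity") <- TRUE
  }
  out
}

#' Write sequences to FASTA
#'
#' @param reference named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(reference, path) {
  reference <- as_reference(reference)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(unname(reference), names(reference))),
    filepath = path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Pileup container and its TSV dialect.
##
## One row per genomic position; per-sample column block
##   <sid>.cov <sid>.nA <sid>.nC <sid>.nG <sid>.nT <sid>.ins <sid>.del
## where ins/del are JSON objects mapping inserted sequence (ins) or deleted
## length (del) to supporting-read counts; "{}" when empty.

#' Construct a multi-sample pileup
#'
#' @param chrom,pos,ref per-position chromosome, 1-based position, reference
#'   base.
#' @param samples sample identifiers (cohort).
#' @param cov integer matrix positions x samples of quality-passing coverage.
#' @param counts list of four matrices `A`, `C`, `G`, `T` with per-base read
#'   counts (same shape as `cov`).
#' @param indels data.frame of sparse indel evidence with columns `row`
#'   (position index), `sample` (sample index), `type` ("ins"/"del"),
#'   `allele` (inserted sequence, or deleted length as character), `count`.
#' @return object of class `pileup`.
#' @export
pileup <- function(chrom, pos, ref, samples, cov, counts,
                   indels = empty_indel_evidence()) {
  n <- length(pos)
  stopifnot(length(chrom) %in% c(1L, n), length(ref) == n,
            nrow(cov) == n, ncol(cov) == length(samples))
  chrom <- rep_len(as.character(chrom), n)
  for (b in BASES) {
    if (!identical(dim(counts[[b]]), dim(cov))) {
      stop("count matrix '", b, "' has wrong shape")
    }
    if (any(counts[[b]] < 0)) stop("negative base count")
  }
  if (any(cov < 0)) stop("negative coverage")
  tot <- counts$A + counts$C + counts$G + counts$T
  if (any(tot > cov)) stop("base counts exceed coverage")
  structure(list(chrom = chrom, pos = as.integer(pos), ref = toupper(ref),
                 samples = as.character(samples), cov = cov, counts = counts,
                 indels = indels),
            class = "pileup")
}

empty_indel_evidence <- function() {
  data.frame(row = integer(), sample = integer(), type = character(),
             allele = character(), count = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup: %d positions x %d samples (%s), %d indel evidence rows\n",
              length(x$pos), length(x$samples),
              paste(x$samples, collapse = ", "), nrow(x$indels)))
  invisible(x)
}

#' Write a pileup to the TSV dialect
#'
#' @param pu a [pileup()].
#' @param path output TSV.
#' @export
write_pileup_tsv <- function(pu, path) {
  n <- length(pu$pos); S <- length(pu$samples)
  ins_json <- matrix("{}", n, S)
  del_json <- matrix("{}", n, S)
  if (nrow(pu$indels)) {
    key <- split(seq_len(nrow(pu$indels)),
                 paste(pu$indels$row, pu$indels$sample, pu$indels$type))
    for (idx in key) {
      r <- pu$indels$row[idx[1]]; s <- pu$indels$sample[idx[1]]
      obj <- as.list(setNames(pu$indels$count[idx], pu$indels$allele[idx]))
      j <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
      if (pu$indels$type[idx[1]] == "ins") ins_json[r, s] <- j
      else del_json[r, s] <- j
    }
  }
  cols <- list(chrom = pu$chrom, pos = pu$pos, ref = pu$ref)
  for (s in seq_len(S)) {
    sid <- pu$samples[s]
    cols[[paste0(sid, ".cov")]] <- pu$cov[, s]
    for (b in BASES) cols[[paste0(sid, ".n", b)]] <- pu$counts[[b]][, s]
    cols[[paste0(sid, ".ins")]] <- ins_json[, s]
    cols[[paste0(sid, ".del")]] <- del_json[, s]
  }
  write.table(as.data.frame(cols, check.names = FALSE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the pileup TSV dialect
#'
#' @param path TSV file written by [write_pileup_tsv()] (or conforming).
#' @param sample_ids expected cohort; the header must declare exactly these
#'   samples (in any order).
#' @return a [pileup()].
#' @export
read_pileup_tsv <- function(path, sample_ids = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   quote = "")
  covcols <- grep("\\.cov$", names(df), value = TRUE)
  found <- sub("\\.cov$", "", covcols)
  if (is.null(sample_ids)) sample_ids <- found
  if (!setequal(found, sample_ids)) {
    stop("pileup header samples (", paste(found, collapse = ","),
         ") do not match declared cohort (",
         paste(sample_ids, collapse = ","), ")")
  }
  need_per_sample <- c(".cov", ".nA", ".nC", ".nG", ".nT", ".ins", ".del")
  expected <- 3L + length(sample_ids) * length(need_per_sample)
  if (ncol(df) != expected) {
    stop(sprintf("pileup column count mismatch: got %d, expected %d",
                 ncol(df), expected))
  }
  n <- nrow(df); S <- length(sample_ids)
  cov <- matrix(0L, n, S)
  counts <- setNames(lapply(BASES, function(b) matrix(0L, n, S)), BASES)
  ind <- list()
  for (s in seq_len(S)) {
    sid <- sample_ids[s]
    cov[, s] <- as.integer(df[[paste0(sid, ".cov")]])
    for (b in BASES) counts[[b]][, s] <- as.integer(df[[paste0(sid, ".n", b)]])
    for (type in c("ins", "del")) {
      col <- df[[paste0(sid, ".", type)]]
      hit <- which(col != "{}")
      for (r in hit) {
        obj <- jsonlite::fromJSON(col[r])
        ind[[length(ind) + 1L]] <- data.frame(
          row = r, sample = s, type = type, allele = names(obj),
          count = as.integer(unlist(obj)), stringsAsFactors = FALSE)
      }
    }
  }
  if (any(cov < 0) || any(vapply(counts, function(m) any(m < 0), logical(1)))) {
    stop("negative count in pileup file ", path)
  }
  indels <- if (length(ind)) do.call(rbind, ind) else empty_indel_evidence()
  pileup(df$chrom, df$pos, df$ref, sample_ids, cov, counts, indels)
}

#' Convert samtools mpileup text to a pileup
#'
#' Ingests the classic 6-columns-per-sample-free mpileup text layout
#' (`chrom pos ref` then per sample `cov bases quals`), applying a base
#' quality filter during conversion: read bases whose Phred quality (offset
#' 33) is below `min_base_quality` are dropped from both base counts and
#' coverage. Indel evidence (`+N...`/`-N...` tags) is attached to the anchor
#' position and counted irrespective of base quality, since mpileup assigns
#' it no quality of its own.
#'
#' @param path mpileup text file.
#' @param sample_ids cohort sample ids, in the column order of the file.
#' @param min_base_quality Phred threshold (default 30).
#' @return a [pileup()].
#' @export
read_mpileup <- function(path, sample_ids, min_base_quality = 30) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines); S <- length(sample_ids)
  chrom <- character(n); pos <- integer(n); ref <- character(n)
  cov <- matrix(0L, n, S)
  counts <- setNames(lapply(BASES, function(b) matrix(0L, n, S)), BASES)
  ind <- list()
  for (r in seq_len(n)) {
    f <- strsplit(lines[r], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L + 3L * S) {
      stop(sprintf("mpileup line %d: expected %d fields, got %d",
                   r, 3L + 3L * S, length(f)))
    }
    chrom[r] <- f[1]; pos[r] <- as.integer(f[2]); ref[r] <- toupper(f[3])
    for (s in seq_len(S)) {
      parsed <- parse_mpileup_bases(f[3L + 3L * s - 1L], f[3L + 3L * s],
                                    ref[r], min_base_quality)
      cov[r, s] <- parsed$cov
      for (b in BASES) counts[[b]][r, s] <- parsed$counts[[b]]
      for (a in names(parsed$ins)) {
        ind[[length(ind) + 1L]] <- data.frame(
          row = r, sample = s, type = "ins", allele = a,
          count = parsed$ins[[a]], stringsAsFactors = FALSE)
      }
      for (a in names(parsed$del)) {
        ind[[length(ind) + 1L]] <- data.frame(
          row = r, sample = s, type = "del", allele = a,
          count = parsed$del[[a]], stringsAsFactors = FALSE)
      }
    }
  }
  indels <- if (length(ind)) do.call(rbind, ind) else empty_indel_evidence()
  pileup(chrom, pos, ref, sample_ids, cov, counts, indels)
}

## Parse one mpileup base string with its quality string. Returns quality-
## filtered per-base counts, coverage, and indel tallies.
parse_mpileup_bases <- function(bases, quals, ref_base, min_q) {
  counts <- setNames(as.list(integer(4)), BASES)
  ins <- list(); del <- list(); covn <- 0L
  if (bases == "*" && quals == "*") {
    return(list(cov = 0L, counts = counts, ins = ins, del = del))
  }
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  qv <- utf8ToInt(quals) - 33L
  i <- 1L; q <- 1L
  while (i <= length(ch)) {
    c0 <- ch[i]
    if (c0 == "^") { i <- i + 2L; next }
    if (c0 == "$") { i <- i + 1L; next }
    if (c0 == "+" || c0 == "-") {
      j <- i + 1L
      while (j <= length(ch) && grepl("[0-9]", ch[j])) j <- j + 1L
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      seqtxt <- toupper(paste(ch[j:(j + len - 1L)], collapse = ""))
      if (c0 == "+") {
        ins[[seqtxt]] <- (if (is.null(ins[[seqtxt]])) 0L else ins[[seqtxt]]) + 1L
      } else {
        key <- as.character(len)
        del[[key]] <- (if (is.null(del[[key]])) 0L else del[[key]]) + 1L
      }
      i <- j + len
      next
    }
    ## a read base with a quality
    pass <- q <= length(qv) && qv[q] >= min_q
    b <- NA_character_
    if (c0 %in% c(".", ",")) b <- ref_base
    else if (toupper(c0) %in% BASES) b <- toupper(c0)
    if (pass) {
      covn <- covn + 1L
      if (!is.na(b) && b %in% BASES && c0 != "*") {
        counts[[b]] <- counts[[b]] + 1L
      }
    }
    q <- q + 1L
    i <- i + 1L
  }
  list(cov = covn, counts = counts, ins = ins, del = del)
}

## ---------------------------------------------------------------------------
## VCF

#' Write mutations to a VCF 4.2 file
#'
#' Indels are emitted with the standard anchored representation: the reference
#' base immediately 5' of the event is prepended to both alleles. The sample
#' of origin is recorded in the INFO field (`SAMPLE=`), as is the mutation
#' class (`CLASS=`).
#'
#' @param muts mutation table, sorted by chrom then pos.
#' @param reference named character vector (needed for indel anchors and
#'   allele consistency checks).
#' @param path output VCF path.
#' @export
write_vcf <- function(muts, reference, path) {
  validate_mutations(muts)
  reference <- as_reference(reference)
  if (nrow(muts) > 1L) {
    o <- order(muts$chrom, muts$pos)
    if (!identical(o, seq_len(nrow(muts)))) {
      stop("mutations must be sorted by chrom, pos before writing VCF")
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            nchar(reference)),
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample carrying the unique mutation\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Mutation class: SNV, INS, DEL or DNV\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(nrow(muts))
  for (k in seq_len(nrow(muts))) {
    m <- muts[k, ]
    seq <- reference[[m$chrom]]
    if (is.null(seq)) stop("chromosome absent from reference: ", m$chrom)
    if (m$mut_class %in% c("SNV", "DNV")) {
      obs <- ref_window(seq, m$pos, m$pos + nchar(m$ref_allele) - 1L)
      if (is.na(obs) || obs != m$ref_allele) {
        stop(sprintf("allele inconsistent with reference at %s:%d",
                     m$chrom, m$pos))
      }
      vpos <- m$pos; vref <- m$ref_allele; valt <- m$alt_allele
    } else if (m$mut_class == "INS") {
      anchor <- ref_window(seq, m$pos, m$pos)
      if (is.na(anchor)) stop(sprintf("insertion anchor out of range at %s:%d",
                                      m$chrom, m$pos))
      vpos <- m$pos; vref <- anchor; valt <- paste0(anchor, m$alt_allele)
    } else { # DEL
      obs <- ref_window(seq, m$pos, m$pos + nchar(m$ref_allele) - 1L)
      if (is.na(obs) || obs != m$ref_allele) {
        stop(sprintf("allele inconsistent with reference at %s:%d",
                     m$chrom, m$pos))
      }
      anchor <- ref_window(seq, m$pos - 1L, m$pos - 1L)
      if (is.na(anchor)) stop(sprintf("deletion anchor out of range at %s:%d",
                                      m$chrom, m$pos))
      vpos <- m$pos - 1L; vref <- paste0(anchor, m$ref_allele); valt <- anchor
    }
    body[k] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSAMPLE=%s;CLASS=%s",
                       m$chrom, vpos, vref, valt, m$sample_id, m$mut_class)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read mutations back from a VCF written by [write_vcf()]
#'
#' Uses vcfR when installed; otherwise falls back to a minimal reader for the
#' subset this package emits. Anchored indels are converted back to the
#' internal unanchored representation.
#'
#' @param path VCF file.
#' @return mutation table.
#' @export
read_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info <- v@fix[, "INFO"]
  } else {
    lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
    if (!length(lines)) return(empty_mutations())
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    fix <- data.frame(CHROM = f[, 1], POS = f[, 2], REF = f[, 4],
                      ALT = f[, 5], stringsAsFactors = FALSE)
    info <- f[, 8]
  }
  if (is.null(fix) || nrow(fix) == 0L) return(empty_mutations())
  sample_id <- sub(".*SAMPLE=([^;]+).*", "\\1", info)
  pos <- as.integer(fix$POS); ref <- fix$REF; alt <- fix$ALT
  nr <- nchar(ref); na <- nchar(alt)
  out <- vector("list", nrow(fix))
  for (k in seq_len(nrow(fix))) {
    if (nr[k] == na[k]) {
      out[[k]] <- list(pos = pos[k], ref = ref[k], alt = alt[k])
    } else if (nr[k] == 1L && na[k] > 1L &&
               substr(alt[k], 1, 1) == ref[k]) {
      out[[k]] <- list(pos = pos[k], ref = "", alt = substring(alt[k], 2))
    } else if (na[k] == 1L && nr[k] > 1L &&
               substr(ref[k], 1, 1) == alt[k]) {
      out[[k]] <- list(pos = pos[k] + 1L, ref = substring(ref[k], 2),
                       alt = "")
    } else {
      stop("unsupported VCF allele representation at line ", k)
    }
  }
  mutations(sample_id = sample_id, chrom = fix$CHROM,
            pos = vapply(out, `[[`, numeric(1), "pos"),
            ref_allele = vapply(out, `[[`, character(1), "ref"),
            alt_allele = vapply(out, `[[`, character(1), "alt"))
}

## ---------------------------------------------------------------------------
## Annotation, expression, signature and triplet tables

#' Read gene annotation from GFF3 or BED
#'
#' GFF3 rows are filtered to `feature_type`; BED intervals (0-based half-open)
#' are converted to 1-based inclusive at the boundary. Returns a GRanges with
#' a `gene_id` column and strand.
#'
#' @param path GFF3 (.gff/.gff3) or BED (.bed) file.
#' @param feature_type GFF3 feature type to keep (default "gene").
#' @param seqlengths optional named vector of chromosome lengths to attach.
#' @return GRanges of gene intervals.
#' @export
read_annotation <- function(path, feature_type = "gene", seqlengths = NULL) {
  gr <- rtracklayer::import(path)
  if (!is.null(gr$type)) {
    gr <- gr[as.character(gr$type) %in% feature_type]
    id <- if (!is.null(gr$ID)) gr$ID else gr$gene_id
  } else {
    id <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
  }
  if (is.null(id)) id <- as.character(seq_along(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = as.character(id))
  if (!is.null(seqlengths)) {
    gr <- GenomicRanges::GRanges(gr)
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                         names(seqlengths))
    GenomeInfoDb::seqlengths(gr)[names(seqlengths)] <- seqlengths
  }
  gr
}

#' Read a gene expression table (gene_id, FPKM)
#'
#' @param path two-column TSV with header `gene_id` and `fpkm` (case
#'   insensitive).
#' @return named numeric vector of FPKM keyed by gene_id.
#' @export
read_fpkm <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("gene_id", "fpkm") %in% names(df))) {
    stop("FPKM table needs columns gene_id and fpkm")
  }
  if (any(df$fpkm < 0)) stop("negative FPKM")
  setNames(df$fpkm, df$gene_id)
}

#' Read a 96-row signature matrix (COSMIC-style TSV)
#'
#' First column holds the channel label (`A[C>A]A` style); remaining columns
#' are signatures. Rows are reordered to the canonical channel order and each
#' signature is checked to sum to 1 within tolerance.
#'
#' @param path TSV file.
#' @param tol unit-sum tolerance (default 1e-6).
#' @return numeric matrix 96 x K with channel rownames.
#' @export
read_signature_matrix <- function(path, tol = 1e-6) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab <- df[[1]]
  if (!setequal(lab, channel_labels())) {
    stop("signature matrix first column must hold the 96 channel labels")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- lab
  m <- m[channel_labels(), , drop = FALSE]
  if (any(m < 0)) stop("negative signature entry")
  s <- colSums(m)
  if (any(abs(s - 1) > tol)) {
    stop("signature(s) not summing to 1: ",
         paste(colnames(m)[abs(s - 1) > tol], collapse = ", "))
  }
  m
}

#' Read / write a triplet frequency table
#'
#' Two-column TSV `triplet<TAB>count` over the 32 strand-folded
#' pyrimidine-centred triplets.
#'
#' @param path TSV file.
#' @return named numeric vector of length 32.
#' @export
read_triplet_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("triplet", "count") %in% names(df))) {
    stop("triplet table needs columns triplet and count")
  }
  if (!setequal(df$triplet, pyrimidine_triplets())) {
    stop("triplet table must cover exactly the 32 pyrimidine-centred triplets")
  }
  if (any(df$count <= 0)) stop("triplet counts must be positive")
  out <- setNames(df$count, df$triplet)[pyrimidine_triplets()]
  out
}

#' @rdname read_triplet_table
#' @param table named numeric vector of 32 triplet counts.
#' @export
write_triplet_table <- function(table, path) {
  write.table(data.frame(triplet = names(table), count = as.numeric(table)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
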