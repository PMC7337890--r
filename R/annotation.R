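#' Load a gene annotation from GFF3
#'
#' Reads `gene`, `five_prime_UTR`, `CDS` and `three_prime_UTR` features from a
#' GFF3 file into the tabular annotation used throughout the package.
#' Chromosome lengths come from `##sequence-region` pragmas, or from a
#' companion two-column lengths table (`name`, `length`) when the pragmas are
#' absent.
#'
#' Coordinates are 1-based inclusive (GFF3 convention). The TSS of a gene is
#' its `start` on the `+` strand and its `end` on the `-` strand; the TTS is
#' the opposite terminus. Sub-genic features may be attached to the gene
#' directly (`Parent=<gene>`) or through an mRNA; for multi-isoform genes the
#' first listed mRNA is used and the number of such genes is reported via a
#' message.
#'
#' @param path Path to a GFF3 file.
#' @param lengths Optional data frame (`name`, `length`) or path to a TSV with
#'   those columns, used when the GFF3 lacks `##sequence-region` pragmas.
#' @return An object of class `te_annotation`: a list with tibbles
#'   \describe{
#'     \item{chroms}{`name`, `length` (bp).}
#'     \item{genes}{`gene_id`, `chrom`, `strand`, `start`, `end`, `tss`,
#'       `tts`, `biotype`.}
#'     \item{features}{`gene_id`, `type` (`five_prime_UTR`/`CDS`/
#'       `three_prime_UTR`), `start`, `end`, sorted and non-overlapping within
#'       a gene and type.}
#'   }
#' @examples
#' gff <- system.file("extdata", "toy_genes.gff3", package = "tetarget")
#' ann <- load_annotation(gff)
#' ann$genes
#' @export
load_annotation <- function(path, lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)

  chroms <- read_sequence_regions(path)
  if (nrow(chroms) == 0L && !is.null(lengths)) {
    if (is.character(lengths)) {
      lengths <- readr::read_tsv(lengths, col_types = readr::cols(
        name = readr::col_character(), length = readr::col_double()
      ))
    }
    chroms <- tibble(name = as.character(lengths$name),
                     length = as.integer(lengths$length))
  }
  if (nrow(chroms) == 0L) {
    abort("no chromosome lengths: GFF3 lacks ##sequence-region pragmas and no lengths table was given")
  }
  if (anyDuplicated(chroms$name)) abort("duplicated chromosome names in lengths")
  if (any(chroms$length < 1)) abort("chromosome lengths must be >= 1")

  gdf <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gdf) == 0L) abort("no gene features found in GFF3")
  gene_id <- gff_id(gdf)
  biotype <- if ("biotype" %in% names(gdf)) as.character(gdf$biotype) else rep(NA_character_, nrow(gdf))
  biotype[is.na(biotype)] <- "protein_coding"
  if (any(gdf$strand == "*")) abort("gene features must be stranded (+/-)")

  genes <- tibble(
    gene_id = gene_id,
    chrom = gdf$seqnames,
    strand = gdf$strand,
    start = as.integer(gdf$start),
    end = as.integer(gdf$end),
    biotype = biotype
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  genes <- genes[, c("gene_id", "chrom", "strand", "start", "end",
                     "tss", "tts", "biotype")]

  glen <- setNames(chroms$length, chroms$name)
  missing_chrom <- setdiff(genes$chrom, chroms$name)
  if (length(missing_chrom) > 0L) {
    abort(paste0("genes on chromosomes absent from the lengths: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  over <- genes$end > glen[genes$chrom]
  if (any(over)) {
    abort(paste0("gene(s) extend past chromosome length: ",
                 paste(genes$gene_id[over], collapse = ", ")))
  }

  # map sub-genic features to genes, through the first mRNA where needed
  feat_types <- c("five_prime_UTR", "CDS", "three_prime_UTR")
  fdf <- df[df$type %in% feat_types, , drop = FALSE]
  features <- empty_features()
  if (nrow(fdf) > 0L) {
    parent <- vapply(fdf$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
    mdf <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
    if (nrow(mdf) > 0L) {
      m_id <- gff_id(mdf)
      m_parent <- vapply(mdf$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
      first_mrna <- tibble(id = m_id, gene = m_parent)
      first_mrna <- first_mrna[!duplicated(first_mrna$gene), , drop = FALSE]
      n_multi <- sum(table(m_parent) > 1L)
      if (n_multi > 0L) {
        inform(paste0(n_multi, " gene(s) have multiple isoforms; using the first listed mRNA"))
      }
      keep_mrna <- setNames(first_mrna$gene, first_mrna$id)
      via_mrna <- parent %in% names(keep_mrna)
      drop <- parent %in% m_id & !via_mrna
      gene_of <- parent
      gene_of[via_mrna] <- keep_mrna[parent[via_mrna]]
      fdf <- fdf[!drop, , drop = FALSE]
      gene_of <- gene_of[!drop]
    } else {
      gene_of <- parent
    }
    features <- tibble(
      gene_id = gene_of,
      type = as.character(fdf$type),
      start = as.integer(fdf$start),
      end = as.integer(fdf$end)
    )
    features <- features[features$gene_id %in% genes$gene_id, , drop = FALSE]
    features <- dplyr::arrange(features, .data$gene_id, .data$type, .data$start)
  }
  validate_features(genes, features)
  new_te_annotation(chroms, genes, features)
}

new_te_annotation <- function(chroms, genes, features) {
  structure(list(chroms = chroms, genes = genes, features = features),
            class = "te_annotation")
}

empty_features <- function() {
  tibble(gene_id = character(), type = character(),
         start = integer(), end = integer())
}

validate_features <- function(genes, features) {
  if (nrow(features) == 0L) return(invisible(TRUE))
  j <- dplyr::left_join(features, genes[, c("gene_id", "start", "end")],
                        by = "gene_id", suffix = c("", ".gene"))
  bad <- j$start < j$start.gene | j$end > j$end.gene | j$start > j$end
  if (any(bad)) {
    abort(paste0("sub-genic feature(s) outside their gene span for: ",
                 paste(unique(j$gene_id[bad]), collapse = ", ")))
  }
  invisible(TRUE)
}

gff_id <- function(df) {
  id <- as.character(df$ID)
  if (anyNA(id)) abort("GFF3 gene/mRNA feature without an ID attribute")
  id
}

read_sequence_regions <- function(path) {
  lines <- readLines(path, n = 5000L)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(sr) == 0L) {
    return(tibble(name = character(), length = integer()))
  }
  parts <- strsplit(trimws(sr), "\\s+")
  tibble(
    name = vapply(parts, `[`, character(1), 2L),
    length = as.integer(vapply(parts, `[`, character(1), 4L))
  )
}

#' @export
print.te_annotation <- function(x, ...) {
  cat("<te_annotation> ", nrow(x$genes), " genes on ", nrow(x$chroms),
      " chromosome(s); ", nrow(x$features), " sub-genic features\n", sep = "")
  invisible(x)
}

#' Write an annotation to GFF3
#'
#' Emits gene and sub-genic features with `##sequence-region` pragmas so the
#' file round-trips through [load_annotation()].
#'
#' @param annotation A `te_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  genes <- annotation$genes
  features <- annotation$features
  gene_rows <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id, biotype = genes$biotype
  )
  rows <- gene_rows
  if (nrow(features) > 0L) {
    fg <- dplyr::left_join(features,
                           genes[, c("gene_id", "chrom", "strand")],
                           by = "gene_id")
    feat_rows <- GenomicRanges::GRanges(
      seqnames = fg$chrom,
      ranges = IRanges::IRanges(fg$start, fg$end),
      strand = fg$strand,
      type = fg$type, ID = NA_character_, Parent = fg$gene_id
    )
    S4Vectors::mcols(gene_rows)$Parent <- NA_character_
    rows <- c(gene_rows, feat_rows)
  }
  rows <- GenomicRanges::sort(rows, ignore.strand = TRUE)
  suppressWarnings(rtracklayer::export(rows, path, format = "gff3"))
  body <- readLines(path)
  pragmas <- sprintf("##sequence-region %s 1 %d",
                     annotation$chroms$name, annotation$chroms$length)
  writeLines(c(body[1L], pragmas, body[-1L]), path)
  invisible(path)
}

#' Signed insertion-to-anchor distance
#'
#' Distance from an insertion position to a gene's TSS or TTS under the
#' genic-positive sign convention: offsets pointing into the gene body are
#' positive for both anchors, offsets pointing away from the gene are
#' negative, and a position exactly at the anchor is 0. All arguments are
#' vectorized and recycled.
#'
#' @param pos Insertion position(s), 1-based bp.
#' @param tss,tts Anchor coordinates of the gene(s).
#' @param strand `"+"` or `"-"` per gene.
#' @param anchor `"TSS"` or `"TTS"`.
#' @return Integer vector of signed distances in bp.
#' @examples
#' signed_distance(1020, tss = 1000, tts = 3000, strand = "+", anchor = "TSS")
#' signed_distance(3020, tss = 1000, tts = 3000, strand = "+", anchor = "TTS")
#' @export
signed_distance <- function(pos, tss, tts, strand, anchor = c("TSS", "TTS")) {
  anchor <- match.arg(anchor)
  sgn <- ifelse(strand == "+", 1L, -1L)
  if (anchor == "TSS") {
    as.integer(sgn * (pos - tss))
  } else {
    as.integer(sgn * (tts - pos))
  }
}

#' Read an insertion set from BED or TSV
#'
#' BED input (0-based half-open) is converted to 1-based points; intervals
#' wider than one base are collapsed to their midpoint and the number of
#' collapsed records is reported. TSV input must have columns `chrom`, `pos`
#' (1-based).
#'
#' @param path Path to a BED (`.bed`) or TSV file.
#' @param label Dataset label stored on the result (defaults to the file
#'   name without extension).
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @return A tibble with columns `chrom`, `pos` and attributes `label`; class
#'   `te_insertions`.
#' @export
read_insertions <- function(path, label = NULL, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    w <- GenomicRanges::width(gr)
    if (any(w > 1L)) {
      inform(paste0(sum(w > 1L), " interval(s) wider than 1 bp collapsed to midpoints"))
    }
    pos <- as.integer(floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2))
    out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)), pos = pos)
  } else {
    out <- readr::read_tsv(path, col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer()
    ))
    out <- out[, c("chrom", "pos")]
  }
  insertion_set(out, label = label)
}

#' Construct an insertion set
#'
#' @param x Data frame with columns `chrom` and `pos` (1-based bp).
#' @param label Dataset label.
#' @param chroms Optional chromosome tibble (`name`, `length`) used to
#'   validate that every position lies within its chromosome.
#' @return A `te_insertions` tibble.
#' @export
insertion_set <- function(x, label = "insertions", chroms = NULL) {
  out <- as_tibble(x[, c("chrom", "pos")])
  out$chrom <- as.character(out$chrom)
  out$pos <- as.integer(out$pos)
  if (any(out$pos < 1L, na.rm = TRUE) || anyNA(out$pos)) {
    abort("insertion positions must be positive integers")
  }
  if (!is.null(chroms)) {
    glen <- setNames(chroms$length, chroms$name)
    if (!all(out$chrom %in% chroms$name)) abort("insertion on unknown chromosome")
    if (any(out$pos > glen[out$chrom])) abort("insertion position beyond chromosome length")
  }
  structure(out, label = label, class = c("te_insertions", class(out)))
}

#' Write an insertion set as sorted BED
#'
#' Emits single-base features (0-based half-open) sorted by chromosome and
#' position.
#'
#' @param insertions A `te_insertions` tibble (or any data frame with `chrom`,
#'   `pos`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_insertions_bed <- function(insertions, path) {
  x <- dplyr::arrange(as_tibble(insertions), .data$chrom, .data$pos)
  gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, width = 1L))
  names(gr) <- NULL
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
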