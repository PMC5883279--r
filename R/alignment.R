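# Codon-alignment container and I/O.
#
# A `codon_alignment` stores sequences as a taxa x sites integer matrix of
# sense-codon indices (1..61). NA marks a gap/ambiguous codon and is permitted
# only before cleaning; cleaned alignments are fully determined.

#' Construct a codon alignment from nucleotide sequences
#'
#' @param seqs named character vector of aligned nucleotide sequences
#'   (equal length, divisible by 3) or a character matrix of single
#'   nucleotides with taxa as rows.
#' @param gene_name label for the gene.
#' @param strip_terminal_stop drop the final codon column when any sequence
#'   ends with an in-frame stop codon.
#' @return object of class `codon_alignment`: list with `gene_name`, `taxa`,
#'   `codons` (taxa x sites integer matrix, values 1..61 or NA for
#'   gap/ambiguous codons) and `n_sites`.
#' @export
codon_alignment <- function(seqs, gene_name = "gene", strip_terminal_stop = TRUE) {
  if (is.matrix(seqs)) {
    seqs <- apply(seqs, 1L, paste0, collapse = "")
  }
  taxa <- names(seqs)
  if (is.null(taxa) || anyDuplicated(taxa) || any(!nzchar(taxa))) {
    stop("sequences must carry unique, non-empty taxon names")
  }
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  lens <- unname(nchar(seqs))
  if (length(unique(lens)) != 1L) {
    stop("format error: sequences have unequal lengths (", paste(unique(lens), collapse = ", "), ")")
  }
  if (lens[1] %% 3L != 0L) {
    stop("frame error: alignment length ", lens[1], " is not divisible by 3")
  }
  n_sites <- lens[1] %/% 3L
  if (n_sites == 0L) stop("empty alignment")
  codon_chr <- t(vapply(seqs, function(s) {
    substring(s, seq(1L, lens[1], by = 3L), seq(3L, lens[1], by = 3L))
  }, character(n_sites)))
  if (n_sites == 1L) codon_chr <- matrix(codon_chr, nrow = length(seqs),
                                         dimnames = list(taxa, NULL))
  # codons with any non-ACGT character (gap, N, IUPAC ambiguity) -> NA sentinel
  clean_nuc <- !grepl("[^ACGT]", codon_chr)
  idx <- matrix(NA_integer_, length(taxa), n_sites, dimnames = list(taxa, NULL))
  idx[clean_nuc] <- CODON_INDEX[codon_chr[clean_nuc]]
  is_stop <- clean_nuc & is.na(idx)
  if (strip_terminal_stop && n_sites > 1L && any(is_stop[, n_sites])) {
    idx <- idx[, -n_sites, drop = FALSE]
    is_stop <- is_stop[, -n_sites, drop = FALSE]
    n_sites <- n_sites - 1L
  }
  if (any(is_stop)) {
    hit <- which(is_stop, arr.ind = TRUE)[1L, ]
    stop("data error: internal stop codon in taxon '", taxa[hit[1]],
         "' at codon site ", hit[2])
  }
  structure(list(gene_name = gene_name, taxa = taxa, codons = idx,
                 n_sites = n_sites),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment '", x$gene_name, "': ", length(x$taxa), " taxa x ",
      x$n_sites, " codon sites", if (anyNA(x$codons)) " (uncleaned)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Recover nucleotide sequences from a codon alignment
#'
#' Gap/ambiguous codons are written as `---`.
#' @param aln a `codon_alignment`.
#' @return named character vector of nucleotide sequences.
#' @export
codon_sequences <- function(aln) {
  chr <- matrix(SENSE_CODONS[aln$codons], nrow(aln$codons))
  chr[is.na(chr)] <- "---"
  stats::setNames(apply(chr, 1L, paste0, collapse = ""), aln$taxa)
}

#' Read a per-gene codon alignment
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"` (relaxed sequential).
#' @param gene_name gene label; defaults to the file base name.
#' @return a `codon_alignment`; terminal stop codons are stripped.
#' @export
read_gene_alignment <- function(path, format = c("fasta", "phylip"),
                                gene_name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(gene_name)) {
    gene_name <- sub("\\.[^.]*$", "", basename(path))
  }
  seqs <- if (format == "fasta") .read_fasta(path) else .read_phylip(path)
  codon_alignment(seqs, gene_name = gene_name)
}

.read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("format error: not a FASTA file: ", path)
  id <- cumsum(hdr)
  nm <- trimws(sub("^>", "", lines[hdr]))
  nm <- vapply(strsplit(nm, "\\s+"), `[`, character(1), 1L)
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) gsub("\\s", "", paste0(x, collapse = "")),
                 character(1))
  stats::setNames(unname(seqs), nm)
}

.read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hd) < 2 || anyNA(suppressWarnings(as.integer(hd[1:2])))) {
    stop("format error: missing PHYLIP header in ", path)
  }
  ntax <- as.integer(hd[1])
  body <- lines[-1]
  if (length(body) < ntax) stop("format error: fewer sequences than declared in ", path)
  # relaxed sequential: name and sequence separated by whitespace, possibly
  # with the sequence continued on following lines
  out <- character(0)
  i <- 1L
  for (k in seq_len(ntax)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    nm <- parts[1]
    sq <- paste0(parts[-1], collapse = "")
    i <- i + 1L
    while (nchar(sq) < as.integer(hd[2]) && i <= length(body)) {
      sq <- paste0(sq, gsub("\\s", "", body[i]))
      i <- i + 1L
    }
    out[nm] <- sq
  }
  out
}

#' Write a codon alignment
#'
#' @param aln a `codon_alignment`.
#' @param path output file.
#' @param format `"fasta"` or `"phylip"`.
#' @export
write_gene_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- codon_sequences(aln)
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  } else {
    writeLines(c(paste(length(seqs), nchar(seqs[1])),
                 paste(format(names(seqs), width = max(nchar(names(seqs)))),
                       unname(seqs))), path)
  }
  invisible(path)
}

#' Remove gap/ambiguous codon columns (complete deletion)
#'
#' Every codon column containing at least one gap or ambiguous codon in any
#' taxon is removed, matching complete-deletion treatment of alignment gaps
#' and uncertainties.
#'
#' @param aln a `codon_alignment`.
#' @return cleaned `codon_alignment` with attribute `provenance`, an integer
#'   vector mapping cleaned column index to original column index (1-based).
#' @export
clean_alignment <- function(aln) {
  keep <- which(colSums(is.na(aln$codons)) == 0L)
  if (length(keep) == 0L) {
    stop("empty-alignment error: all codon columns of '", aln$gene_name,
         "' contain gaps or ambiguities")
  }
  prov <- attr(aln, "provenance")
  out <- structure(list(gene_name = aln$gene_name, taxa = aln$taxa,
                        codons = aln$codons[, keep, drop = FALSE],
                        n_sites = length(keep)),
                   class = "codon_alignment")
  attr(out, "provenance") <- if (is.null(prov)) keep else prov[keep]
  out
}

#' Extract within-codon nucleotide positions
#'
#' @param aln cleaned `codon_alignment`.
#' @param positions subset of 1:3, e.g. `c(1, 2)` for the
#'   saturation-robust first and second codon positions.
#' @return character matrix (taxa x nucleotide sites) of nucleotides.
#' @export
extract_codon_positions <- function(aln, positions) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0L || any(!positions %in% 1:3)) {
    stop("argument error: positions must be a non-empty subset of 1:3")
  }
  if (anyNA(aln$codons)) stop("alignment must be cleaned first")
  nuc_idx <- lapply(positions, function(p) CODON_NUC[aln$codons, p])
  m <- matrix(NA_integer_, length(aln$taxa), aln$n_sites * length(positions))
  for (k in seq_along(positions)) {
    m[, seq(k, ncol(m), by = length(positions))] <-
      matrix(nuc_idx[[k]], length(aln$taxa))
  }
  matrix(NUCS[m], nrow(m), dimnames = list(aln$taxa, NULL))
}

#' Read a gene-to-functional-class table
#'
#' Two tab-separated columns: gene name, class label (e.g. `photosynthesis`
#' or `genetic_system`).
#' @param path TSV path.
#' @return named character vector gene -> class.
#' @export
read_class_map <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tb) < 2) stop("format error: class map needs two tab-separated columns")
  if (anyDuplicated(tb[[1]])) stop("data error: duplicated gene in class map")
  stats::setNames(as.character(tb[[2]]), as.character(tb[[1]]))
}

#' Concatenate gene alignments by functional class
#'
#' @param genes list of cleaned `codon_alignment` objects sharing one taxon set.
#' @param classes named character vector gene -> class label.
#' @return named list, one concatenated `codon_alignment` per class, each with
#'   attribute `boundaries`: data frame (gene, start, end) of 1-based codon
#'   offsets so concatenated sites map back to (gene, within-gene site).
#' @export
concatenate_by_class <- function(genes, classes) {
  gene_names <- vapply(genes, function(g) g$gene_name, character(1))
  missing_cls <- setdiff(gene_names, names(classes))
  if (length(missing_cls)) {
    stop("data error: no functional class for gene(s): ",
         paste(missing_cls, collapse = ", "))
  }
  ref_taxa <- sort(genes[[1]]$taxa)
  for (g in genes) {
    if (!identical(sort(g$taxa), ref_taxa)) {
      stop("data error: taxon set of '", g$gene_name, "' differs; missing: ",
           paste(setdiff(ref_taxa, g$taxa), collapse = ", "))
    }
  }
  out <- list()
  for (cls in unique(classes[gene_names])) {
    members <- genes[classes[gene_names] == cls]
    mats <- lapply(members, function(g) g$codons[ref_taxa, , drop = FALSE])
    lens <- vapply(members, function(g) g$n_sites, integer(1))
    cat_aln <- structure(list(
      gene_name = cls, taxa = ref_taxa, codons = do.call(cbind, mats),
      n_sites = sum(lens)), class = "codon_alignment")
    attr(cat_aln, "boundaries") <- data.frame(
      gene = vapply(members, function(g) g$gene_name, character(1)),
      start = cumsum(c(1L, lens[-length(lens)])),
      end = cumsum(lens), row.names = NULL)
    out[[cls]] <- cat_aln
  }
  out
}

#' Map a concatenated site back to its source gene
#'
#' @param site 1-based codon site in the concatenated alignment.
#' @param boundaries the `boundaries` attribute of a concatenated alignment.
#' @return data frame with columns `gene` and `site` (within-gene, 1-based).
#' @export
map_concatenated_site <- function(site, boundaries) {
  row <- findInterval(site, boundaries$start)
  if (any(row < 1L | site > boundaries$end[row])) {
    stop("site outside concatenated range")
  }
  data.frame(gene = boundaries$gene[row],
             site = site - boundaries$start[row] + 1L)
}

#' Translate a cleaned codon alignment to amino acids
#'
#' @param aln cleaned `codon_alignment`.
#' @return object of class `aa_alignment`: list with `gene_name`, `taxa`,
#'   `aa` (taxa x sites integer matrix over 1..20, alphabetical single-letter
#'   order) and `n_sites`.
#' @export
translate_alignment <- function(aln) {
  if (anyNA(aln$codons)) {
    stop("data error: alignment contains gap/ambiguous codons; clean first")
  }
  structure(list(gene_name = aln$gene_name, taxa = aln$taxa,
                 aa = codon_to_aa_index(aln$codons), n_sites = aln$n_sites),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment '", x$gene_name, "': ", length(x$taxa), " taxa x ",
      x$n_sites, " residues\n", sep = "")
  invisible(x)
}
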