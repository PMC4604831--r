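#' @keywords internal
#' @useDynLib quartetcoal, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Read and write the standard file formats
#'
#' Thin wrappers around the field-standard readers with the package's
#' coordinate conventions: genomic intervals are 0-based half-open
#' internally and in BED files; variant tables are 1-based in files.
#'
#' @name io
NULL

#' @rdname io
#' @param path file path.
#' @return `read_trees`: list of `phylo`.
#' @export
read_trees <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed newick in ", path)
  if (inherits(tr, "phylo")) list(tr) else unclass(tr)
}

#' @rdname io
#' @param trees list of `phylo`.
#' @export
write_trees <- function(trees, path) {
  ape::write.tree(do.call(c, trees), file = path)
  invisible(path)
}

#' @rdname io
#' @return `read_species_map`: named character vector haplotype -> species.
#' @export
read_species_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("haplotype", "species"),
                          colClasses = "character")
  stats::setNames(df$species, df$haplotype)
}

#' @rdname io
#' @param species_map named character vector.
#' @export
write_species_map <- function(species_map, path) {
  utils::write.table(data.frame(names(species_map), unname(species_map)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param variants variant data.frame (`chrom`, `pos` 1-based, `anc`, `der`,
#'   one column per haplotype with 0/1/`.`).
#' @export
write_variants <- function(variants, path) {
  v <- variants
  hap <- setdiff(names(v), c("chrom", "pos", "anc", "der"))
  for (h in hap) v[[h]] <- ifelse(is.na(v[[h]]), ".", as.character(v[[h]]))
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_variants <- function(path) {
  v <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, colClasses = "character")
  v$pos <- as.integer(v$pos)
  hap <- setdiff(names(v), c("chrom", "pos", "anc", "der"))
  for (h in hap) {
    x <- suppressWarnings(as.numeric(ifelse(v[[h]] == ".", NA, v[[h]])))
    v[[h]] <- x
  }
  v
}

#' @rdname io
#' @return `read_bed`: data.frame `chrom`, `start`, `end` (0-based,
#'   half-open — identical to the file convention).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df[1:3]
}

#' @rdname io
#' @param intervals data.frame `chrom`, `start`, `end`.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals[c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# FASTA writer for a haplotypes x sites character matrix
write_fasta_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(">", rownames(m)[i]), con)
    writeLines(paste(m[i, ], collapse = ""), con)
  }
  invisible(path)
}

# FASTA reader returning the same matrix layout
read_fasta_matrix <- function(path) {
  dn <- ape::read.FASTA(path)
  ch <- as.character(dn)
  m <- do.call(rbind, ch)
  m <- toupper(m)
  rownames(m) <- names(dn)
  m
}

#' @rdname io
#' @param sfs an [sfs2d()].
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# joint derived-allele SFS %s-%s; %d+%d chromosomes; %.0f sites",
                     sfs$pair[1], sfs$pair[2], sfs$n[1], sfs$n[2],
                     sfs$total_sites), con)
  writeLines(paste(c("d/d", paste0(sfs$pair[2], "_", 0:sfs$n[2])),
                   collapse = "\t"), con)
  for (i in 0:sfs$n[1])
    writeLines(paste(c(paste0(sfs$pair[1], "_", i),
                       format(sfs$counts[i + 1, ], trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname io
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hd <- lines[1]
  m <- regmatches(hd, regexec(
    "SFS (\\S+)-(\\S+); (\\d+)\\+(\\d+) chromosomes; (\\d+) sites", hd))[[1]]
  if (length(m) != 6) stop("malformed SFS header at line 1")
  body <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                            row.names = 1)
  counts <- as.matrix(body)
  dimnames(counts) <- NULL
  sfs2d(counts, pair = m[2:3], total_sites = as.numeric(m[6]))
}
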