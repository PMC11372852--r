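## Alignment container and sequence simulation along trees.
## Alignments are plain character matrices (rows = taxa, columns = sites,
## lower-case a/c/g/t plus "-" for missing data).

#' Coerce to an alignment matrix
#'
#' @param x Character matrix with row names, or a list of equal-length
#'   character vectors named by taxon.
#' @return Character matrix with unique row names.
#' @export
as_alignment_matrix <- function(x) {
  if (is.list(x) && !is.matrix(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) != 1L) stop("ragged sequences")
    x <- do.call(rbind, x)
  }
  if (!is.matrix(x) || !is.character(x)) stop("not an alignment matrix")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("alignment rows must carry unique taxon names")
  x
}

#' Simulate an alignment along a tree
#'
#' Evolves i.i.d. sites down the tree: the root state is drawn from the
#' model's stationary frequencies, each site is assigned one of the
#' discrete-gamma rate categories independently, and states change along
#' each branch according to [transition_matrix()] at the branch length
#' times the site's category rate.
#'
#' @param tree A `"phylo"` object with branch lengths in expected
#'   substitutions per site.
#' @param model An `"sba_model"`.
#' @param K Number of sites `>= 1`.
#' @return Alignment matrix (taxa x sites).
#' @export
simulate_alignment <- function(tree, model, K) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "sba_model"), K >= 1)
  ntip <- ape::Ntip(tree)
  if (ntip < 2) stop("tree must have at least 2 leaves")
  tr <- stats::reorder(tree, "postorder")
  ncat <- if (is.null(model$alpha)) 1L else model$ncat
  rates <- if (ncat == 1L) 1 else gamma_rates(model$alpha, ncat)
  cat_i <- if (ncat == 1L) rep(1L, K) else sample.int(ncat, K, replace = TRUE)
  states <- matrix(0L, max(tr$edge), K)
  states[ntip + 1L, ] <- sample.int(4, K, replace = TRUE, prob = model$bf)
  for (i in rev(seq_len(nrow(tr$edge)))) {   # preorder traversal
    par <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    t <- tr$edge.length[i]
    for (cc in seq_len(ncat)) {
      P <- transition_matrix(model, t, rates[cc])
      for (s in 1:4) {
        idx <- which(states[par, ] == s & cat_i == cc)
        if (length(idx))
          states[ch, idx] <- sample.int(4, length(idx), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }
  m <- matrix(BASES[states[seq_len(ntip), , drop = FALSE]], ntip, K)
  rownames(m) <- tr$tip.label
  m
}

#' Identical sequences for four taxa
#'
#' One sequence drawn i.i.d. uniform over the four bases, replicated for
#' S1..S4: the fully uninformative input on which a fair ML engine must
#' return each resolved topology with probability 1/3.
#'
#' @param K Number of sites.
#' @param taxa Taxon labels (default S1..S4).
#' @return Alignment matrix.
#' @export
make_identical_alignment <- function(K, taxa = paste0("S", 1:4)) {
  stopifnot(K >= 1)
  row <- sample(BASES, K, replace = TRUE)
  m <- matrix(rep(row, each = length(taxa)), length(taxa), K)
  rownames(m) <- taxa
  m
}

#' Saturated (independent) sequences
#'
#' Every cell is drawn independently from `freqs`, emulating sequences
#' evolved past saturation so that taxa are mutually independent.
#'
#' @param K Number of sites.
#' @param freqs Base frequencies (A, C, G, T) summing to 1; the defaults
#'   are the unequal frequencies used in the saturation scenario.
#' @param taxa Taxon labels.
#' @return Alignment matrix.
#' @export
make_saturated_alignment <- function(K, freqs = c(0.1, 0.2, 0.3, 0.4),
                                     taxa = paste0("S", 1:4)) {
  stopifnot(K >= 1, length(freqs) == 4)
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("freqs must be non-negative and sum to 1")
  m <- matrix(sample(BASES, length(taxa) * K, replace = TRUE, prob = freqs),
              length(taxa), K)
  rownames(m) <- taxa
  m
}

#' Delete a fraction of sites in selected taxa
#'
#' Replaces `round(fraction * K)` positions, chosen uniformly without
#' replacement per listed taxon, with the gap symbol `-`.
#'
#' @param alignment Alignment matrix.
#' @param fraction Proportion of sites to remove, in `[0, 1]`.
#' @param taxa Labels of the rows to degrade.
#' @return Alignment matrix with gaps.
#' @export
apply_missing <- function(alignment, fraction, taxa) {
  m <- as_alignment_matrix(alignment)
  stopifnot(fraction >= 0, fraction <= 1)
  if (!all(taxa %in% rownames(m)))
    stop("unknown taxon: ", paste(setdiff(taxa, rownames(m)), collapse = ", "))
  ndrop <- round(fraction * ncol(m))
  for (tx in taxa) {
    idx <- sample.int(ncol(m), ndrop)
    m[tx, idx] <- "-"
  }
  m
}

#' Write an alignment as FASTA
#' @param alignment Alignment matrix.
#' @param file Output path.
#' @export
write_fasta <- function(alignment, file) {
  m <- as_alignment_matrix(alignment)
  con <- file(file, "w"); on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(">", rownames(m)[i]), con)
    writeLines(paste(m[i, ], collapse = ""), con)
  }
  invisible(file)
}

#' Read a FASTA alignment
#' @param file Input path.
#' @return Alignment matrix (lower-case bases).
#' @export
read_fasta <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", file)
  names <- sub("^>\\s*", "", lines[hdr])
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- mapply(function(a, b) {
    tolower(paste(lines[seq(a + 1L, b)], collapse = ""))
  }, hdr, ends)
  m <- do.call(rbind, lapply(strsplit(seqs, ""), identity))
  rownames(m) <- names
  as_alignment_matrix(m)
}

#' Write an alignment in relaxed PHYLIP format
#' @param alignment Alignment matrix.
#' @param file Output path.
#' @export
write_phylip <- function(alignment, file) {
  m <- as_alignment_matrix(alignment)
  con <- file(file, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(rownames(m)[i], paste(m[i, ], collapse = "")), con)
  invisible(file)
}

#' Read a relaxed PHYLIP alignment
#' @param file Input path.
#' @return Alignment matrix.
#' @export
read_phylip <- function(file) {
  lines <- readLines(file)
  dims <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- rows[lengths(rows) == 2L]
  if (length(rows) != dims[1]) stop("PHYLIP header does not match content")
  m <- do.call(rbind, lapply(rows, function(r) strsplit(tolower(r[2]), "")[[1]]))
  rownames(m) <- vapply(rows, `[[`, "", 1L)
  if (ncol(m) != dims[2]) stop("PHYLIP header does not match content")
  as_alignment_matrix(m)
}
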