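#' @importFrom stats optim rbinom rbeta rexp rpois runif sd var cor setNames
#' @importFrom utils combn read.csv write.csv read.table write.table
NULL

VALID_BASES <- c("A", "C", "G", "T", "-", "N")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Aligned DNA sequence matrix
#'
#' Constructs a `dna_alignment`: a character matrix of aligned sequences,
#' one row per individual, one column per site, over the alphabet
#' {A, C, G, T, -, N}.  Lower-case input is normalised to upper case;
#' ambiguity codes other than N are converted to N with a warning.
#'
#' @param seqs named character vector of equal-length sequence strings, or a
#'   character matrix with row names.
#' @return A `dna_alignment` object.
#' @export
dna_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
    ids <- rownames(m)
  } else {
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named")
    seqs <- toupper(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("alignment error: ragged sequence lengths (",
           paste(unique(lens), collapse = ", "), ")")
    }
    if (lens[1] == 0L) stop("alignment error: zero-length sequences")
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- ids
  }
  if (anyDuplicated(ids)) {
    stop("input error: duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- !(m %in% VALID_BASES)
  if (any(bad)) {
    warning(sum(bad), " ambiguous/unknown characters converted to N")
    m[bad] <- "N"
  }
  structure(list(ids = ids, mat = m), class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("dna_alignment:", length(x$ids), "sequences x", ncol(x$mat), "sites\n")
  invisible(x)
}

#' @export
length.dna_alignment <- function(x) length(x$ids)

#' Number of aligned sites
#' @param aln a `dna_alignment`.
#' @return integer site count.
#' @export
n_sites <- function(aln) ncol(aln$mat)

#' Subset an alignment by individual ids
#' @param aln a `dna_alignment`.
#' @param ids ids to keep, in the order given.
#' @return a `dna_alignment`.
#' @export
subset_alignment <- function(aln, ids) {
  miss <- setdiff(ids, aln$ids)
  if (length(miss)) stop("ids not in alignment: ", paste(miss, collapse = ", "))
  dna_alignment(aln$mat[ids, , drop = FALSE])
}

#' Read an aligned FASTA file with a population table
#'
#' @param path FASTA file of aligned sequences.
#' @param population_table data frame with columns `id`, `population` and
#'   optionally `region`, or path to a delimited file (whitespace/tab/comma)
#'   with those columns.
#' @return list with elements `alignment` (a [dna_alignment]) and
#'   `pop_map` (data frame id/population/region).
#' @export
read_fasta_alignment <- function(path, population_table = NULL) {
  d <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = FALSE)
  if (!is.list(d)) d <- list(d)  # single record
  seqs <- vapply(d, function(s) paste(toupper(s), collapse = ""), "")
  names(seqs) <- names(d)
  aln <- dna_alignment(seqs)
  pm <- NULL
  if (!is.null(population_table)) {
    pm <- as_pop_map(population_table)
    missing_ids <- setdiff(aln$ids, pm$id)
    if (length(missing_ids)) {
      stop("input error: ids missing from population table: ",
           paste(missing_ids, collapse = ", "))
    }
    pm <- pm[match(aln$ids, pm$id), , drop = FALSE]
    rownames(pm) <- NULL
  }
  list(alignment = aln, pop_map = pm)
}

#' Coerce to a population map
#'
#' @param x data frame with columns id/population (optionally region), or a
#'   path to a delimited text file with those columns.
#' @return data frame with columns `id`, `population`, `region`.
#' @export
as_pop_map <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- read.table(x, header = TRUE, sep = "", stringsAsFactors = FALSE,
                    comment.char = "#")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("id", "population")
  if (!all(need %in% names(x))) {
    stop("population table needs columns 'id' and 'population'")
  }
  if (is.null(x$region)) x$region <- "all"
  x$id <- as.character(x$id)
  x$population <- as.character(x$population)
  x$region <- as.character(x$region)
  if (anyDuplicated(x$id)) stop("input error: duplicate ids in population table")
  x[, c("id", "population", "region")]
}

#' Write an alignment as FASTA
#' @param aln a `dna_alignment`.
#' @param path output file.
#' @param annotations optional named character vector appended to headers.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, annotations = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in aln$ids) {
    hdr <- if (!is.null(annotations) && !is.na(annotations[id])) {
      paste0(">", id, " ", annotations[id])
    } else paste0(">", id)
    writeLines(c(hdr, paste(aln$mat[id, ], collapse = "")), con)
  }
  invisible(path)
}

#' Concatenate two alignments over the same individuals
#'
#' Joins fragment `a` (5') to fragment `b` (3') per individual; the result
#' has length `k_a + k_b`.  The id sets must be identical.
#'
#' @param a,b `dna_alignment` objects.
#' @return a `dna_alignment` of the concatenated sequences, in `a`'s order.
#' @export
concatenate_alignments <- function(a, b) {
  if (n_sites(b) == 0L || length(b$ids) == 0L) return(a)
  if (length(a$ids) == 0L || n_sites(a) == 0L) return(b)
  dif <- c(setdiff(a$ids, b$ids), setdiff(b$ids, a$ids))
  if (length(dif)) {
    stop("id mismatch between fragments: ", paste(dif, collapse = ", "))
  }
  dna_alignment(cbind(a$mat, b$mat[a$ids, , drop = FALSE]))
}

#' Collapse an alignment into haplotypes
#'
#' Identical sequences (exact string match after upper-casing; missing data
#' are not wild cards) are merged.  Haplotypes are numbered in order of first
#' occurrence.
#'
#' @param aln a `dna_alignment`.
#' @param pop_map population map (see [as_pop_map]); if NULL all individuals
#'   form one population "all".
#' @return a `haplotype_table`: list with `sequences` (named character
#'   vector, names Hap01...), `counts` (haplotype x population integer
#'   matrix), `n` (total individuals), `assignment` (haplotype label per
#'   individual).
#' @export
collapse_haplotypes <- function(aln, pop_map = NULL) {
  if (length(aln$ids) == 0L) stop("empty alignment")
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  if (is.null(pop_map)) {
    pop_map <- data.frame(id = aln$ids, population = "all", region = "all",
                          stringsAsFactors = FALSE)
  } else {
    pop_map <- as_pop_map(pop_map)
  }
  pops <- pop_map$population[match(aln$ids, pop_map$id)]
  if (anyNA(pops)) {
    stop("input error: ids missing from population table: ",
         paste(aln$ids[is.na(pops)], collapse = ", "))
  }
  uniq <- unique(seqs)
  hap_id <- match(seqs, uniq)
  labels <- sprintf("Hap%02d", seq_along(uniq))
  pop_levels <- unique(pops)
  counts <- table(factor(hap_id, levels = seq_along(uniq)),
                  factor(pops, levels = pop_levels))
  counts <- matrix(as.integer(counts), nrow = length(uniq),
                   dimnames = list(labels, pop_levels))
  structure(list(sequences = setNames(uniq, labels), counts = counts,
                 n = length(seqs), assignment = setNames(labels[hap_id], aln$ids)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$sequences), "haplotypes from", x$n,
      "individuals across", ncol(x$counts), "population(s)\n")
  invisible(x)
}

#' Expand a haplotype table back to an alignment
#'
#' Inverse of [collapse_haplotypes] up to individual labels: reproduces the
#' multiset of sequences implied by the counts.
#'
#' @param ht a `haplotype_table`.
#' @return a `dna_alignment` with synthetic ids `<hap>_<pop>_<i>`.
#' @export
expand_haplotypes <- function(ht) {
  out <- character(0)
  for (h in rownames(ht$counts)) for (p in colnames(ht$counts)) {
    cnt <- ht$counts[h, p]
    if (cnt > 0) {
      v <- rep(ht$sequences[[h]], cnt)
      names(v) <- sprintf("%s_%s_%d", h, p, seq_len(cnt))
      out <- c(out, v)
    }
  }
  dna_alignment(out)
}

#' Classify alignment sites
#'
#' A site is variable when it carries >= 2 distinct non-missing, non-gap
#' states; parsimony-informative when >= 2 states are each carried by >= 2
#' sequences.  Substitution type is transition (purine-purine or
#' pyrimidine-pyrimidine), transversion, or mixed (>2 states or both kinds).
#' Sites containing a gap are flagged indel; indel-only variation (a site
#' whose non-gap states are all identical) is counted separately from
#' substitution variation.
#'
#' @param aln a `dna_alignment`.
#' @return a `site_summary`: data frame per site (`site`, `variable`,
#'   `parsimony_informative`, `subst_type`, `indel`) with an attached
#'   `counts` attribute (k, invariant, variable, parsimony_informative,
#'   transitions, transversions, mixed, indel_sites, indel_only).
#' @export
classify_sites <- function(aln) {
  k <- n_sites(aln)
  m <- aln$mat
  nA <- colSums(m == "A"); nC <- colSums(m == "C")
  nG <- colSums(m == "G"); nT <- colSums(m == "T")
  has_gap <- colSums(m == "-") > 0
  n_states <- (nA > 0) + (nC > 0) + (nG > 0) + (nT > 0)
  variable <- n_states >= 2L
  pi <- ((nA >= 2) + (nC >= 2) + (nG >= 2) + (nT >= 2)) >= 2L
  st <- rep(NA_character_, k)
  two <- n_states == 2L
  is_ts <- (nA > 0 & nG > 0 & nC == 0 & nT == 0) |
    (nC > 0 & nT > 0 & nA == 0 & nG == 0)
  st[two & is_ts] <- "transition"
  st[two & !is_ts] <- "transversion"
  st[n_states > 2L] <- "mixed"
  df <- data.frame(site = seq_len(k), variable = variable,
                   parsimony_informative = pi, subst_type = st,
                   indel = has_gap, stringsAsFactors = FALSE, row.names = NULL)
  counts <- c(
    k = k,
    invariant = sum(!df$variable & !df$indel),
    variable = sum(df$variable),
    parsimony_informative = sum(df$parsimony_informative),
    transitions = sum(df$subst_type == "transition", na.rm = TRUE),
    transversions = sum(df$subst_type == "transversion", na.rm = TRUE),
    mixed = sum(df$subst_type == "mixed", na.rm = TRUE),
    indel_sites = sum(df$indel),
    indel_only = sum(df$indel & !df$variable)
  )
  attr(df, "counts") <- counts
  class(df) <- c("site_summary", "data.frame")
  df
}

#' Pairwise sequence difference counts
#'
#' Number of differing sites per unordered pair under pairwise deletion:
#' positions where either sequence has '-' or 'N' are excluded for that pair.
#' The count matrix need not satisfy the triangle inequality when deletion
#' patterns differ between pairs.
#'
#' @param aln a `dna_alignment`.
#' @param effective_length also return the per-pair number of compared sites?
#' @return symmetric integer matrix of difference counts (ids as dimnames);
#'   when `effective_length = TRUE`, a list with `diff` and `sites`.
#' @export
pairwise_differences <- function(aln, effective_length = FALSE) {
  m <- aln$mat
  n <- nrow(m)
  valid <- m != "-" & m != "N"
  # integer coding; invalid positions get 0 so equality tests are masked below
  code <- matrix(match(m, c("A", "C", "G", "T"), nomatch = 0L), nrow = n)
  D <- matrix(0L, n, n, dimnames = list(aln$ids, aln$ids))
  L <- matrix(ncol(m), n, n, dimnames = list(aln$ids, aln$ids))
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        ok <- valid[i, ] & valid[j, ]
        D[i, j] <- D[j, i] <- sum(code[i, ok] != code[j, ok])
        L[i, j] <- L[j, i] <- sum(ok)
      }
    }
  }
  if (effective_length) list(diff = D, sites = L) else D
}

#' Export a haplotype table
#'
#' Writes the haplotype sequences as FASTA (frequencies annotated in the
#' description line) and the count matrix as CSV.
#'
#' @param ht a `haplotype_table`.
#' @param fasta_path,csv_path output files (either may be NULL to skip).
#' @return invisibly, a list of the paths written.
#' @export
export_haplotypes <- function(ht, fasta_path = NULL, csv_path = NULL) {
  if (!is.null(fasta_path)) {
    ann <- vapply(rownames(ht$counts), function(h) {
      paste0("n=", sum(ht$counts[h, ]), " [",
             paste(sprintf("%s:%d", colnames(ht$counts), ht$counts[h, ]),
                   collapse = ","), "]")
    }, "")
    write_fasta_alignment(dna_alignment(ht$sequences), fasta_path,
                          annotations = ann)
  }
  if (!is.null(csv_path)) {
    write.csv(as.data.frame(ht$counts), csv_path)
  }
  invisible(list(fasta = fasta_path, csv = csv_path))
}
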