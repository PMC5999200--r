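#' @useDynLib gsimix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom dplyr %>%
NULL

META_COLS <- c("indiv", "collection", "repunit")

#' Locus names of a genotype table
#'
#' A genotype table is a tibble with columns `indiv`, optionally
#' `collection` and `repunit`, followed by two character columns per locus
#' (`Locus`, `Locus.1`) holding allele labels, `NA` for missing calls.
#'
#' @param x a genotype table.
#' @return character vector of locus names.
#' @export
geno_loci <- function(x) {
  cols <- setdiff(names(x), META_COLS)
  loci <- cols[!grepl("\\.1$", cols)]
  expect2 <- as.vector(rbind(loci, paste0(loci, ".1")))
  if (!identical(cols, expect2)) {
    stop("genotype columns must come in pairs <locus>, <locus>.1; got an odd ",
         "or misordered set", call. = FALSE)
  }
  loci
}

#' @keywords internal
validate_geno <- function(x) {
  if (!"indiv" %in% names(x)) stop("genotype table needs an 'indiv' column", call. = FALSE)
  if (anyDuplicated(x$indiv)) {
    stop("duplicate individual ID(s): ",
         paste(unique(x$indiv[duplicated(x$indiv)]), collapse = ", "), call. = FALSE)
  }
  invisible(geno_loci(x))
}

# Two N x L character matrices of allele labels (a1 sorted <= a2), NA missing.
#' @keywords internal
allele_mats <- function(x) {
  loci <- geno_loci(x)
  a1 <- as.matrix(as.data.frame(x[, loci, drop = FALSE]))
  a2 <- as.matrix(as.data.frame(x[, paste0(loci, ".1"), drop = FALSE]))
  colnames(a1) <- colnames(a2) <- loci
  rownames(a1) <- rownames(a2) <- x$indiv
  # a call with either allele missing is wholly missing
  bad <- is.na(a1) | is.na(a2)
  a1[bad] <- NA_character_
  a2[bad] <- NA_character_
  swap <- !bad & allele_order(a1) > allele_order(a2)
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  list(a1 = a1, a2 = a2, indiv = x$indiv, loci = loci)
}

# numeric-aware ordering key for allele labels
#' @keywords internal
allele_order <- function(v) {
  num <- suppressWarnings(as.numeric(v))
  ifelse(is.na(num) & !is.na(v), rank_chr(v), num)
}

#' @keywords internal
rank_chr <- function(v) {
  u <- sort(unique(v[!is.na(v)]))
  # offset so mixed numeric/string labels still order deterministically
  1e9 + match(v, u)
}

#' @keywords internal
sort_alleles <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) labels[order(num)] else sort(labels)
}

# rebuild a genotype table from allele matrices (sorted-pair normalized)
#' @keywords internal
mats_to_geno <- function(a1, a2, indiv, collection = NULL, repunit = NULL) {
  loci <- colnames(a1)
  out <- tibble::tibble(indiv = indiv)
  if (!is.null(collection)) out$collection <- collection
  if (!is.null(repunit)) out$repunit <- repunit
  gcols <- vector("list", 2L * length(loci))
  names(gcols) <- as.vector(rbind(loci, paste0(loci, ".1")))
  for (j in seq_along(loci)) {
    gcols[[2L * j - 1L]] <- unname(a1[, j])
    gcols[[2L * j]] <- unname(a2[, j])
  }
  dplyr::bind_cols(out, tibble::as_tibble(gcols))
}

#' Drop individuals with too much missing data
#'
#' Removes individuals whose fraction of missing locus calls is strictly
#' greater than `max_missing_frac` (default 0.5, i.e. the ">50% missing"
#' baseline-cleaning rule).
#'
#' @param x genotype table.
#' @param max_missing_frac maximum tolerated missing fraction; individuals
#'   strictly above it are removed.
#' @return list with `genotypes` (the filtered table) and `removed`
#'   (tibble of `indiv`, `missing_frac` for the dropped individuals).
#' @export
filter_missing_individuals <- function(x, max_missing_frac = 0.5) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  validate_geno(x)
  m <- allele_mats(x)
  frac <- rowMeans(is.na(m$a1))
  drop <- frac > max_missing_frac
  list(
    genotypes = x[!drop, , drop = FALSE],
    removed = tibble::tibble(indiv = x$indiv[drop], missing_frac = frac[drop])
  )
}

#' Build a per-locus allele index
#'
#' Maps each distinct allele label at each locus to a dense integer index
#' (1..A_l, in sorted label order; numeric-looking labels sort numerically).
#'
#' @param x genotype table, or a list of genotype tables whose alleles should
#'   share one index (e.g. baseline plus mixture).
#' @return object of class `allele_index`: a named list (locus -> character
#'   vector of allele labels) with attributes `n_alleles` (per locus),
#'   `total_alleles` and `mean_alleles` (to 1 decimal). Loci with zero
#'   non-missing calls get a zero-length entry and are listed in the
#'   `empty_loci` attribute.
#' @export
build_allele_index <- function(x) {
  tabs <- if (is.data.frame(x)) list(x) else x
  loci <- geno_loci(tabs[[1]])
  for (t in tabs) {
    if (!identical(geno_loci(t), loci)) stop("tables have different loci", call. = FALSE)
  }
  idx <- lapply(seq_along(loci), function(j) {
    labs <- unlist(lapply(tabs, function(t) {
      m <- allele_mats(t)
      c(m$a1[, j], m$a2[, j])
    }), use.names = FALSE)
    sort_alleles(unique(labs[!is.na(labs)]))
  })
  names(idx) <- loci
  nA <- vapply(idx, length, integer(1))
  structure(idx,
            class = "allele_index",
            n_alleles = nA,
            total_alleles = sum(nA),
            mean_alleles = round(sum(nA) / length(nA), 1),
            empty_loci = names(nA)[nA == 0L])
}

#' @export
print.allele_index <- function(x, ...) {
  cat("allele_index:", length(x), "loci,",
      attr(x, "total_alleles"), "alleles (mean",
      attr(x, "mean_alleles"), "per locus)\n")
  invisible(x)
}

# integer-coded genotypes: list(a1, a2) N x L integer matrices into the index
#' @keywords internal
encode_genotypes <- function(x, index) {
  m <- allele_mats(x)
  if (!identical(m$loci, names(index))) stop("loci do not match allele index", call. = FALSE)
  a1 <- matrix(NA_integer_, nrow(m$a1), ncol(m$a1), dimnames = dimnames(m$a1))
  a2 <- a1
  for (j in seq_along(index)) {
    i1 <- match(m$a1[, j], index[[j]])
    i2 <- match(m$a2[, j], index[[j]])
    if (anyNA(i1[!is.na(m$a1[, j])]) || anyNA(i2[!is.na(m$a2[, j])])) {
      stop("allele at locus '", names(index)[j],
           "' not present in allele index; build the index on the union of tables",
           call. = FALSE)
    }
    a1[, j] <- i1
    a2[, j] <- i2
  }
  list(a1 = a1, a2 = a2, indiv = m$indiv, loci = m$loci)
}

#' Per-collection allele counts
#'
#' Tallies gene copies by collection, locus and allele — the sufficient
#' statistic for the mixture likelihood machinery.
#'
#' @param x genotype table with a `collection` column (no NAs).
#' @param index optional `allele_index`; built from `x` if omitted.
#' @return object of class `allele_counts`: list with `x` (per locus, a
#'   C x A_l integer matrix of allele counts), `n` (C x L matrix of gene
#'   copies, 2 x non-missing individuals), `collections`, `loci`, `index`,
#'   `n_indiv` (individuals per collection) and `ru_map` (named character
#'   vector collection -> reporting unit, if `repunit` present).
#' @export
allele_counts <- function(x, index = NULL) {
  validate_geno(x)
  if (is.null(x[["collection"]]) || anyNA(x[["collection"]])) {
    stop("allele_counts() needs a fully labeled 'collection' column", call. = FALSE)
  }
  if (is.null(index)) index <- build_allele_index(x)
  enc <- encode_genotypes(x, index)
  collections <- unique(x[["collection"]])
  C <- length(collections); L <- length(enc$loci)
  ci <- match(x[["collection"]], collections)
  n <- matrix(0L, C, L, dimnames = list(collections, enc$loci))
  xs <- vector("list", L); names(xs) <- enc$loci
  for (j in seq_len(L)) {
    A <- length(index[[j]])
    cnt <- matrix(0L, C, A, dimnames = list(collections, if (A) index[[j]] else NULL))
    ok <- !is.na(enc$a1[, j])
    if (any(ok)) {
      tab <- table(factor(rep(ci[ok], 2), levels = seq_len(C)),
                   factor(c(enc$a1[ok, j], enc$a2[ok, j]), levels = seq_len(A)))
      cnt[, seq_len(A)] <- as.integer(tab)
      n[, j] <- as.integer(rowSums(cnt))
    }
    xs[[j]] <- cnt
  }
  ru_map <- NULL
  if (!is.null(x[["repunit"]]) && !anyNA(x[["repunit"]])) {
    ru_map <- tapply(x[["repunit"]], ci, function(v) v[1])
    ru_map <- stats::setNames(as.character(ru_map), collections)
  }
  structure(list(x = xs, n = n, collections = collections, loci = enc$loci,
                 index = index,
                 n_indiv = as.integer(table(factor(ci, levels = seq_len(C)))),
                 ru_map = ru_map),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("allele_counts:", length(x$collections), "collections x",
      length(x$loci), "loci;", attr(x$index, "total_alleles"), "alleles\n")
  invisible(x)
}

#' Reporting-unit map of a genotype table
#'
#' @param x labeled genotype table.
#' @return named character vector, collection -> reporting unit. Collections
#'   without a `repunit` column map to themselves.
#' @export
ru_map_of <- function(x) {
  collections <- unique(x[["collection"]])
  if (is.null(x[["repunit"]])) return(stats::setNames(collections, collections))
  m <- vapply(collections, function(cc) {
    u <- unique(x[["repunit"]][x[["collection"]] == cc])
    if (length(u) != 1L) stop("collection '", cc, "' maps to several reporting units", call. = FALSE)
    u
  }, character(1))
  m
}
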