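#' Read a genotype table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`"wide"`}{CSV with header `indiv[,collection[,repunit]],LocusA,LocusA.1,...`
#'     — two character allele columns per locus. Cells equal to any string in
#'     `missing` (or empty) are treated as missing calls.}
#'   \item{`"genepop"`}{classic genepop with 4-digit allele codes, `0000`
#'     (or `000000`) missing; `Pop` separators delimit collections, which are
#'     named `pop_1`, `pop_2`, ... in file order.}
#' }
#' Heterozygote call order is normalized on read, so `(a,b)` and `(b,a)`
#' are the same genotype.
#'
#' @param path file path.
#' @param dialect `"wide"` or `"genepop"`.
#' @param missing character vector of cell values that denote a missing
#'   allele call in the wide dialect.
#' @return genotype table (tibble); see [geno_loci()] for the layout.
#' @export
read_genotypes <- function(path, dialect = c("wide", "genepop"),
                           missing = c("", "0", "NA", "000", "0000")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- switch(dialect,
              wide = read_geno_wide(path, missing),
              genepop = read_genepop(path))
  validate_geno(x)
  m <- allele_mats(x)  # normalizes pair order / half-missing calls
  mats_to_geno(m$a1, m$a2, x$indiv, x[["collection"]], x[["repunit"]])
}

#' @keywords internal
read_geno_wide <- function(path, missing) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE, show_col_types = FALSE)
  for (cc in setdiff(names(x), META_COLS)) {
    v <- x[[cc]]
    v[v %in% missing] <- NA_character_
    x[[cc]] <- v
  }
  x
}

#' @keywords internal
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a genepop file: ", path, call. = FALSE)
  body <- lines[-1]  # first line is a title/comment
  is_pop <- toupper(trimws(body)) %in% c("POP")
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("genepop file has no 'Pop' line", call. = FALSE)
  locus_block <- body[seq_len(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_block, ",")))
  loci <- loci[nzchar(loci)]
  recs <- body[-seq_len(first_pop - 1L)]
  pop_id <- cumsum(toupper(trimws(recs)) == "POP")
  recs_keep <- recs[toupper(trimws(recs)) != "POP"]
  pop_id <- pop_id[toupper(trimws(recs)) != "POP"]
  parse_rec <- function(line) {
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed genepop record: ", line, call. = FALSE)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[[:space:]]+")[[1]]
    if (length(codes) != length(loci)) {
      stop("individual '", id, "' has ", length(codes), " genotypes for ",
           length(loci), " loci", call. = FALSE)
    }
    list(id = id, codes = codes)
  }
  parsed <- lapply(recs_keep, parse_rec)
  N <- length(parsed); L <- length(loci)
  a1 <- matrix(NA_character_, N, L, dimnames = list(NULL, loci))
  a2 <- a1
  for (i in seq_len(N)) {
    codes <- parsed[[i]]$codes
    w <- nchar(codes) %/% 2L
    if (any(nchar(codes) %% 2L != 0L)) {
      stop("odd-width genepop allele code for individual '", parsed[[i]]$id, "'", call. = FALSE)
    }
    c1 <- substr(codes, 1L, w)
    c2 <- substr(codes, w + 1L, 2L * w)
    v1 <- as.integer(c1); v2 <- as.integer(c2)
    a1[i, ] <- ifelse(is.na(v1) | v1 == 0L, NA_character_, as.character(v1))
    a2[i, ] <- ifelse(is.na(v2) | v2 == 0L, NA_character_, as.character(v2))
  }
  mats_to_geno(a1, a2, vapply(parsed, `[[`, character(1), "id"),
               collection = paste0("pop_", pop_id))
}

#' Write a genotype table
#'
#' @param x genotype table.
#' @param path output file.
#' @param dialect `"wide"` CSV (missing written as empty cells) or
#'   `"genepop"` (4-digit allele codes; labels must be integers < 10000;
#'   individuals are grouped by `collection` in first-appearance order).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, dialect = c("wide", "genepop")) {
  dialect <- match.arg(dialect)
  validate_geno(x)
  if (dialect == "wide") {
    readr::write_csv(x, path, na = "")
    return(invisible(path))
  }
  m <- allele_mats(x)
  num <- suppressWarnings(matrix(as.integer(m$a1), nrow(m$a1)))
  if (anyNA(num[!is.na(m$a1)]) || any(num >= 10000, na.rm = TRUE)) {
    stop("genepop output needs integer allele labels < 10000", call. = FALSE)
  }
  code <- function(v) {
    iv <- suppressWarnings(as.integer(v))
    out <- sprintf("%04d", ifelse(is.na(iv), 0L, iv))
    out
  }
  geno <- matrix(paste0(code(m$a1), code(m$a2)), nrow(m$a1))
  coll <- if (is.null(x[["collection"]])) rep("pop_1", nrow(x)) else x[["collection"]]
  pops <- unique(coll)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("gsimix genepop export", m$loci), con)
  for (p in pops) {
    writeLines("Pop", con)
    idx <- which(coll == p)
    writeLines(paste0(m$indiv[idx], " ,  ",
                      apply(geno[idx, , drop = FALSE], 1, paste, collapse = " ")), con)
  }
  invisible(path)
}
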