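#' Multi-allelic diploid genotype panels
#'
#' A `genotype_panel` holds genotypes for `I` diploid individuals at `L`
#' unlinked, codominant, multi-allelic loci (microsatellite/STR-style data).
#' Internally alleles are recoded to dense 1-based indices per locus; the
#' original integer allele codes are retained so that file output round-trips.
#'
#' @param genotypes integer array of dimension `I x L x 2` with 1-based allele
#'   indices, `NA` for missing. Both allele copies of a genotype must be
#'   missing together.
#' @param individual_ids character vector of length `I`.
#' @param allele_codes list of length `L`; element `l` maps dense index
#'   `1..A_l` to the original allele code at locus `l`.
#' @param subpop_labels optional a-priori subpopulation labels (length `I`).
#'
#' @return an object of class `genotype_panel` with fields `X` (the genotype
#'   array), `ids`, `subpop`, `n_ind`, `n_loci`, `n_alleles` (per-locus allele
#'   counts `A_l`) and `allele_codes`.
#' @export
genotype_panel <- function(genotypes, individual_ids = NULL,
                           allele_codes = NULL, subpop_labels = NULL) {
  if (length(dim(genotypes)) != 3L || dim(genotypes)[3] != 2L)
    stop("`genotypes` must be an I x L x 2 array")
  I <- dim(genotypes)[1]
  L <- dim(genotypes)[2]
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(I))
  if (length(individual_ids) != I) stop("individual_ids has wrong length")
  storage.mode(genotypes) <- "integer"

  half <- xor(is.na(genotypes[, , 1, drop = FALSE]),
              is.na(genotypes[, , 2, drop = FALSE]))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf("half-missing genotype for individual %s at locus %d",
                 individual_ids[idx[1]], idx[2]))
  }
  A <- integer(L)
  for (l in seq_len(L)) {
    obs <- genotypes[, l, ][!is.na(genotypes[, l, ])]
    A[l] <- if (length(obs)) max(obs) else 0L
    if (length(obs) && (min(obs) < 1L))
      stop(sprintf("allele index < 1 at locus %d", l))
  }
  if (is.null(allele_codes)) {
    allele_codes <- lapply(A, function(a) seq_len(a))
  } else {
    if (length(allele_codes) != L) stop("allele_codes has wrong length")
    for (l in seq_len(L))
      if (length(allele_codes[[l]]) < A[l])
        stop(sprintf("allele_codes[[%d]] shorter than observed alleles", l))
    A <- pmax(A, lengths(allele_codes))
  }
  if (!is.null(subpop_labels) && length(subpop_labels) != I)
    stop("subpop_labels has wrong length")
  structure(list(X = genotypes, ids = as.character(individual_ids),
                 subpop = subpop_labels, n_ind = I, n_loci = L,
                 n_alleles = as.integer(A), allele_codes = allele_codes),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  n_miss <- sum(is.na(x$X[, , 1]))
  cat(sprintf("genotype_panel: %d individuals x %d loci\n", x$n_ind, x$n_loci))
  cat(sprintf("  alleles per locus: %s (range %d-%d)\n",
              paste(utils::head(x$n_alleles, 8), collapse = ","),
              min(x$n_alleles), max(x$n_alleles)))
  cat(sprintf("  missing genotypes: %d (%.1f%%)\n", n_miss,
              100 * n_miss / (x$n_ind * x$n_loci)))
  if (!is.null(x$subpop))
    cat(sprintf("  a-priori subpopulations: %d\n",
                length(unique(x$subpop))))
  invisible(x)
}

#' Read a STRUCTURE-format genotype file
#'
#' Reads whitespace-delimited multi-allelic genotype panels in the two common
#' STRUCTURE dialects: two rows per individual (one allele copy per row), or
#' one row per individual with two adjacent columns per locus. Allele codes
#' are arbitrary integers and are recoded to dense per-locus indices; the
#' original codes are kept on the returned panel for round-tripping.
#'
#' @param path file path.
#' @param missing_code integer code marking a missing allele (default -9).
#' @param dialect `"auto"` (default), `"two_row"` or `"one_row"`. Auto
#'   detection: if every individual label occurs on exactly two consecutive
#'   rows the file is treated as two-row, otherwise one-row (which requires an
#'   even number of genotype columns).
#' @param popcol logical; does column 2 hold an a-priori subpopulation label?
#' @return a [genotype_panel()].
#' @export
read_structure <- function(path, missing_code = -9L,
                           dialect = c("auto", "two_row", "one_row"),
                           popcol = FALSE) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("ragged rows: line %d has %d fields, line 1 has %d",
                 which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1],
                 ncols[1]))
  ids_raw <- vapply(toks, `[[`, "", 1L)
  meta <- if (popcol) 2L else 1L
  n_data <- ncols[1] - meta
  if (n_data < 1L) stop("no genotype columns found")

  if (dialect == "auto") {
    two_row_ok <- length(ids_raw) %% 2L == 0L &&
      all(ids_raw[seq(1, length(ids_raw), by = 2)] ==
            ids_raw[seq(2, length(ids_raw), by = 2)])
    dialect <- if (two_row_ok) "two_row" else "one_row"
  }

  parse_num <- function(tok, line) {
    v <- suppressWarnings(as.integer(tok))
    if (anyNA(v))
      stop(sprintf("non-integer allele code on line %d", line))
    v
  }

  if (dialect == "two_row") {
    if (length(ids_raw) %% 2L != 0L)
      stop("two-row dialect: odd number of rows")
    first <- seq(1, length(ids_raw), by = 2)
    if (any(ids_raw[first] != ids_raw[first + 1])) {
      bad <- first[which(ids_raw[first] != ids_raw[first + 1])[1]]
      stop(sprintf("two-row dialect: rows %d and %d have different labels (%s, %s)",
                   bad, bad + 1, ids_raw[bad], ids_raw[bad + 1]))
    }
    I <- length(first)
    L <- n_data
    X <- array(NA_integer_, c(I, L, 2))
    sub <- if (popcol) character(I) else NULL
    ids <- ids_raw[first]
    for (i in seq_len(I)) {
      r1 <- parse_num(toks[[first[i]]][(meta + 1):ncols[1]], first[i])
      r2 <- parse_num(toks[[first[i] + 1]][(meta + 1):ncols[1]], first[i] + 1)
      X[i, , 1] <- r1
      X[i, , 2] <- r2
      if (popcol) sub[i] <- toks[[first[i]]][2]
    }
  } else {
    if (n_data %% 2L != 0L)
      stop("one-row dialect: odd number of genotype columns")
    I <- length(ids_raw)
    L <- n_data %/% 2L
    X <- array(NA_integer_, c(I, L, 2))
    sub <- if (popcol) character(I) else NULL
    ids <- ids_raw
    for (i in seq_len(I)) {
      v <- parse_num(toks[[i]][(meta + 1):ncols[1]], i)
      X[i, , 1] <- v[seq(1, 2 * L, by = 2)]
      X[i, , 2] <- v[seq(2, 2 * L, by = 2)]
      if (popcol) sub[i] <- toks[[i]][2]
    }
  }

  X[X == missing_code] <- NA_integer_
  half <- xor(is.na(X[, , 1, drop = FALSE]), is.na(X[, , 2, drop = FALSE]))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf("half-missing genotype for individual %s at locus %d",
                 ids[idx[1]], idx[2]))
  }

  codes <- vector("list", L)
  Xr <- array(NA_integer_, dim(X))
  for (l in seq_len(L)) {
    obs <- sort(unique(X[, l, ][!is.na(X[, l, ])]))
    codes[[l]] <- obs
    if (length(obs)) {
      Xr[, l, 1] <- match(X[, l, 1], obs)
      Xr[, l, 2] <- match(X[, l, 2], obs)
    }
  }
  genotype_panel(Xr, ids, allele_codes = codes, subpop_labels = sub)
}

#' Write a panel back to STRUCTURE format
#'
#' Inverse of [read_structure()]: dense allele indices are mapped back to the
#' panel's original allele codes.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @param missing_code integer written for missing alleles.
#' @param dialect `"two_row"` or `"one_row"`.
#' @export
write_structure <- function(panel, path, missing_code = -9L,
                            dialect = c("two_row", "one_row")) {
  dialect <- match.arg(dialect)
  I <- panel$n_ind; L <- panel$n_loci
  decode <- function(i, m) {
    v <- integer(L)
    for (l in seq_len(L)) {
      a <- panel$X[i, l, m]
      v[l] <- if (is.na(a)) missing_code else panel$allele_codes[[l]][a]
    }
    v
  }
  con <- file(path, "w")
  on.exit(close(con))
  popfield <- function(i)
    if (is.null(panel$subpop)) character(0) else as.character(panel$subpop[i])
  for (i in seq_len(I)) {
    if (dialect == "two_row") {
      writeLines(paste(c(panel$ids[i], popfield(i), decode(i, 1)),
                       collapse = " "), con)
      writeLines(paste(c(panel$ids[i], popfield(i), decode(i, 2)),
                       collapse = " "), con)
    } else {
      g <- rbind(decode(i, 1), decode(i, 2))
      writeLines(paste(c(panel$ids[i], popfield(i), as.vector(g)),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

#' Reduce a panel to per-individual allele counts
#'
#' Sufficient statistics for the admixture-model likelihood: `n[[l]][i, a]` is
#' the number of copies of allele `a` that individual `i` carries at locus
#' `l` (0, 1 or 2). Missing genotypes yield an all-zero row, so each
#' non-missing (individual, locus) cell contributes exactly two allele copies.
#'
#' @param panel a [genotype_panel()].
#' @return object of class `allele_counts`: a list of length `L` of
#'   `I x A_l` integer matrices, with attributes `n_ind` and `n_loci`.
#' @export
to_allele_counts <- function(panel) {
  I <- panel$n_ind; L <- panel$n_loci
  n <- vector("list", L)
  for (l in seq_len(L)) {
    m <- matrix(0L, I, max(panel$n_alleles[l], 1L))
    for (i in seq_len(I)) {
      a1 <- panel$X[i, l, 1]; a2 <- panel$X[i, l, 2]
      if (!is.na(a1)) {
        m[i, a1] <- m[i, a1] + 1L
        m[i, a2] <- m[i, a2] + 1L
      }
    }
    n[[l]] <- m
  }
  structure(n, class = "allele_counts", n_ind = I, n_loci = L)
}

#' Write ancestry (Q) and allele-frequency (P) matrices as TSV
#'
#' `Q` is written as `<prefix>_Q.tsv` (one row per individual, one column per
#' subpopulation), `P` as `<prefix>_P.tsv` in long format
#' (`subpop`, `locus`, `allele`, `freq`) so that jagged per-locus allele
#' counts survive a round-trip. Values carry 12 significant digits.
#'
#' @param fit an [admixture_fit] (see [fit_admixture()]).
#' @param prefix path prefix for the two output files.
#' @return invisibly, the two file paths.
#' @export
write_qp_matrices <- function(fit, prefix) {
  stopifnot(inherits(fit, "admixture_fit"))
  qf <- paste0(prefix, "_Q.tsv")
  pf <- paste0(prefix, "_P.tsv")
  q <- data.frame(id = rownames(fit$eta) %||% paste0("ind", seq_len(nrow(fit$eta))),
                  signif(fit$eta, 12), check.names = FALSE)
  names(q)[-1] <- paste0("Q", seq_len(fit$K))
  utils::write.table(q, qf, sep = "\t", quote = FALSE, row.names = FALSE)
  rows <- list()
  for (l in seq_along(fit$p)) {
    pl <- fit$p[[l]]  # K x A_l
    rows[[l]] <- data.frame(subpop = rep(seq_len(nrow(pl)), ncol(pl)),
                            locus = l,
                            allele = rep(seq_len(ncol(pl)), each = nrow(pl)),
                            freq = signif(as.vector(pl), 12))
  }
  utils::write.table(do.call(rbind, rows), pf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(qf, pf))
}

#' Read Q/P matrices written by [write_qp_matrices()]
#'
#' @param prefix path prefix used when writing.
#' @return an `admixture_fit` object (without a log-likelihood trace).
#' @export
read_qp_matrices <- function(prefix) {
  q <- utils::read.table(paste0(prefix, "_Q.tsv"), header = TRUE, sep = "\t",
                         check.names = FALSE)
  p <- utils::read.table(paste0(prefix, "_P.tsv"), header = TRUE, sep = "\t")
  eta <- as.matrix(q[, -1, drop = FALSE])
  rownames(eta) <- q[[1]]
  K <- ncol(eta)
  if (max(p$subpop) != K)
    stop(sprintf("K mismatch between Q (%d) and P (%d)", K, max(p$subpop)))
  L <- max(p$locus)
  plist <- vector("list", L)
  for (l in seq_len(L)) {
    sub <- p[p$locus == l, ]
    m <- matrix(0, K, max(sub$allele))
    m[cbind(sub$subpop, sub$allele)] <- sub$freq
    plist[[l]] <- m
  }
  new_admixture_fit(K = K, eta = eta, p = plist, loglik_trace = numeric(0),
                    converged = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
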