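#' Construct and validate a pedigree
#'
#' Builds a validated pedigree object from a data frame of family links.
#' Founder status and generation number (0 = founder) are derived; the
#' structure is checked for cycles, duplicate individuals, unknown parent
#' ids and parent links crossing family boundaries.
#'
#' @param df data frame with columns `family`, `id`, `father`, `mother`,
#'   `sex`. Parent columns use `NA` (or `"0"`) for a missing parent. `sex`
#'   is `"male"`/`"female"`/`"unknown"` or PED codes 1/2/0.
#' @return A `famvar_pedigree`: the input with derived columns `founder`
#'   (logical, both parents missing) and `generation` (integer, 0 for
#'   founders, otherwise 1 + max parental generation).
#' @examples
#' ped <- as_pedigree(data.frame(
#'   family = "F1", id = c("p1", "p2", "c1"),
#'   father = c(NA, NA, "p1"), mother = c(NA, NA, "p2"),
#'   sex = c("male", "female", "female")))
#' ped$generation
#' @export
as_pedigree <- function(df) {
  need <- c("family", "id", "father", "mother", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pedigree is missing columns: ", paste(miss, collapse = ", "))
  ped <- data.frame(
    family = as.character(df$family),
    id = as.character(df$id),
    father = as.character(df$father),
    mother = as.character(df$mother),
    sex = decode_sex(df$sex),
    stringsAsFactors = FALSE
  )
  ped$father[!is.na(ped$father) & ped$father == "0"] <- NA_character_
  ped$mother[!is.na(ped$mother) & ped$mother == "0"] <- NA_character_

  if (anyDuplicated(ped$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  fam_of <- stats::setNames(ped$family, ped$id)
  for (col in c("father", "mother")) {
    p <- ped[[col]]
    known <- !is.na(p)
    bad <- known & !(p %in% ped$id)
    if (any(bad)) {
      stop("unknown ", col, " id(s): ", paste(unique(p[bad]), collapse = ", "))
    }
    cross <- known & fam_of[p] != ped$family
    if (any(cross[known])) {
      stop("parent link crosses families for individual(s): ",
           paste(ped$id[which(cross)], collapse = ", "))
    }
    self <- known & p == ped$id
    if (any(self)) stop("individual is its own parent: ",
                        paste(ped$id[self], collapse = ", "))
  }

  ped$founder <- is.na(ped$father) & is.na(ped$mother)
  ped$generation <- ped_generations(ped)
  class(ped) <- c("famvar_pedigree", "data.frame")
  ped
}

decode_sex <- function(x) {
  if (is.numeric(x)) x <- as.character(x)
  x <- as.character(x)
  out <- rep("unknown", length(x))
  out[x %in% c("1", "male", "M", "m")] <- "male"
  out[x %in% c("2", "female", "F", "f")] <- "female"
  out
}

# Generation by iterative relaxation; a failure to converge means a cycle.
ped_generations <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- ifelse(is.na(ped$father), NA_integer_, idx[ped$father])
  mo <- ifelse(is.na(ped$mother), NA_integer_, idx[ped$mother])
  gen <- rep(NA_integer_, n)
  gen[is.na(fa) & is.na(mo)] <- 0L
  for (pass in seq_len(n + 1L)) {
    todo <- which(is.na(gen))
    if (!length(todo)) return(gen)
    for (i in todo) {
      gf <- if (is.na(fa[i])) 0L else gen[fa[i]]
      gm <- if (is.na(mo[i])) 0L else gen[mo[i]]
      if (!is.na(gf) && !is.na(gm)) gen[i] <- 1L + max(gf, gm)
    }
  }
  stop("pedigree contains a cycle involving individual(s): ",
       paste(ped$id[is.na(gen)], collapse = ", "))
}

#' Pedigree kinship matrix
#'
#' Computes kinship coefficients phi by the recursive tabular method,
#' processing each family in generation order: phi(i,i) = (1 + phi(f_i,
#' m_i))/2 and phi(i,j) = (phi(f_i,j) + phi(m_i,j))/2 for previously
#' processed j, with a missing parent contributing 0 (treated as an
#' unrelated founder). Individuals in different families have phi = 0.
#'
#' @param ped a `famvar_pedigree` (see [as_pedigree()]).
#' @return Symmetric matrix of kinship coefficients with individual ids as
#'   dimnames and the family of each individual in `attr(,"family")`.
#'   `2 * phi` is the expected additive genetic covariance scaling.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   family = "F1", id = c("p1", "p2", "s1", "s2"),
#'   father = c(NA, NA, "p1", "p1"), mother = c(NA, NA, "p2", "p2"),
#'   sex = c(1, 2, 1, 2)))
#' kinship(ped)["s1", "s2"]  # full sibs: 0.25
#' @export
kinship <- function(ped) {
  stopifnot(inherits(ped, "famvar_pedigree"))
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  idx <- stats::setNames(seq_len(n), ped$id)
  for (fam in unique(ped$family)) {
    rows <- which(ped$family == fam)
    rows <- rows[order(ped$generation[rows])]
    k <- length(rows)
    fa <- match(ped$father[rows], ped$id[rows])
    mo <- match(ped$mother[rows], ped$id[rows])
    block <- matrix(0, k, k)
    for (a in seq_len(k)) {
      f <- fa[a]; m <- mo[a]
      block[a, a] <- 0.5 * (1 + if (!is.na(f) && !is.na(m)) block[f, m] else 0)
      if (a > 1L) {
        for (b in seq_len(a - 1L)) {
          v <- 0
          if (!is.na(f)) v <- v + block[f, b]
          if (!is.na(m)) v <- v + block[m, b]
          block[a, b] <- block[b, a] <- 0.5 * v
        }
      }
    }
    phi[rows, rows] <- block
  }
  attr(phi, "family") <- stats::setNames(ped$family, ped$id)
  phi
}

#' Eigendecomposition of a block-diagonal relatedness matrix
#'
#' The additive relationship matrix 2*phi is block diagonal by family, so
#' its eigendecomposition is taken per block. The result is reused across
#' all variants (and permutations) tested against one phenotype.
#'
#' @param K symmetric PSD matrix (typically `2 * kinship(ped)`), with a
#'   `family` attribute or block structure discoverable from its sparsity.
#' @return list with `values` (eigenvalues, length n), `blocks` (per-block
#'   list of `idx` and eigenvector matrix `U`), and `n`. Use
#'   [kinship_transform()] to apply t(U) to vectors/matrices.
#' @export
kinship_eigen <- function(K) {
  n <- nrow(K)
  fam <- attr(K, "family")
  if (is.null(fam)) {
    comp <- block_components(K)
  } else {
    comp <- split(seq_len(n), fam[rownames(K)])
  }
  values <- numeric(n)
  blocks <- vector("list", length(comp))
  pos <- 1L
  for (i in seq_along(comp)) {
    idx <- comp[[i]]
    e <- eigen(K[idx, idx, drop = FALSE], symmetric = TRUE)
    slot <- seq.int(pos, pos + length(idx) - 1L)
    values[slot] <- e$values
    blocks[[i]] <- list(idx = idx, slot = slot, U = e$vectors)
    pos <- pos + length(idx)
  }
  if (min(values) < -1e-8 * max(abs(values))) {
    stop("relatedness matrix is not positive semidefinite")
  }
  list(values = pmax(values, 0), blocks = blocks, n = n)
}

# connected components of the non-zero pattern (fallback when no family attr)
block_components <- function(K) {
  n <- nrow(K)
  seen <- rep(FALSE, n)
  comp <- list()
  adj <- abs(K) > 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    members <- s
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nb] <- TRUE
      members <- c(members, nb)
      frontier <- nb
    }
    comp[[length(comp) + 1L]] <- sort(members)
  }
  comp
}

#' Apply the eigenvector rotation of a kinship decomposition
#'
#' Computes `t(U) %*% x` (or `U %*% x` with `inverse = TRUE`) blockwise.
#'
#' @param decomp result of [kinship_eigen()].
#' @param x vector or matrix with `decomp$n` rows.
#' @param inverse rotate back (multiply by U rather than t(U)).
#' @return rotated vector/matrix; rows are in eigenvalue slot order.
#' @export
kinship_transform <- function(decomp, x, inverse = FALSE) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  out <- matrix(0, nrow(x), ncol(x))
  for (b in decomp$blocks) {
    if (inverse) {
      out[b$idx, ] <- b$U %*% x[b$slot, , drop = FALSE]
    } else {
      out[b$slot, ] <- crossprod(b$U, x[b$idx, , drop = FALSE])
    }
  }
  if (vec) out[, 1L] else out
}

#' Read / write PED-style pedigree files
#'
#' Whitespace-delimited, columns family, individual, father, mother, sex
#' (1 = male, 2 = female, 0 = unknown); `"0"` denotes a missing parent.
#'
#' @param path file path.
#' @return [read_ped()] returns a validated `famvar_pedigree`.
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 5) stop("PED file must have >= 5 columns")
  names(df)[1:5] <- c("family", "id", "father", "mother", "sex")
  as_pedigree(df[, 1:5])
}

#' @param ped pedigree to write.
#' @rdname read_ped
#' @export
write_ped <- function(ped, path) {
  stopifnot(inherits(ped, "famvar_pedigree"))
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  out <- data.frame(ped$family, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    sex)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export / import a kinship matrix as TSV
#'
#' TSV with a header row and first column of individual ids.
#'
#' @param phi kinship matrix from [kinship()].
#' @param path file path.
#' @export
write_kinship <- function(phi, path) {
  df <- data.frame(id = rownames(phi), phi, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(ids, colnames(df)[-1])
  m
}
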