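#' Construct an ncRNA-disease association dataset
#'
#' Bundles the binary association matrix `RD` (ncRNAs in rows, diseases in
#' columns) with the node identifier lists and, optionally, the ncRNA-ncRNA
#' and disease-disease similarity matrices. This object is the single source
#' of truth for one benchmark: every graph construction, embedding engine and
#' evaluation routine consumes it.
#'
#' @param RD binary matrix, `r x d`; entries must be 0/1.
#' @param rna_ids,disease_ids unique character identifiers for rows/columns
#'   of `RD`; defaults are taken from `dimnames(RD)` or generated.
#' @param SR,SD optional similarity matrices in `[0, 1]` (`r x r`, `d x d`);
#'   must be symmetric (tolerance `1e-8`) with unit diagonal.
#' @return an object of class `association_dataset` with fields `rna_ids`,
#'   `disease_ids`, `RD`, `SR`, `SD`.
#' @export
association_dataset <- function(RD, rna_ids = NULL, disease_ids = NULL,
                                SR = NULL, SD = NULL) {
  RD <- as.matrix(RD)
  if (is.null(rna_ids)) {
    rna_ids <- rownames(RD)
    if (is.null(rna_ids)) rna_ids <- paste0("R", seq_len(nrow(RD)))
  }
  if (is.null(disease_ids)) {
    disease_ids <- colnames(RD)
    if (is.null(disease_ids)) disease_ids <- paste0("D", seq_len(ncol(RD)))
  }
  if (anyDuplicated(rna_ids)) stop("duplicate ncRNA identifiers")
  if (anyDuplicated(disease_ids)) stop("duplicate disease identifiers")
  if (length(rna_ids) != nrow(RD) || length(disease_ids) != ncol(RD)) {
    stop("identifier lists do not match RD dimensions")
  }
  if (!all(RD %in% c(0, 1))) stop("RD entries must be 0 or 1")
  check_sim <- function(S, n, what) {
    if (is.null(S)) return(NULL)
    S <- as.matrix(S)
    if (nrow(S) != n || ncol(S) != n) {
      stop(sprintf("%s must be %d x %d", what, n, n))
    }
    if (max(abs(S - t(S))) > 1e-8) stop(sprintf("%s is not symmetric", what))
    if (max(abs(diag(S) - 1)) > 1e-8) stop(sprintf("%s diagonal is not 1", what))
    if (min(S) < 0 || max(S) > 1) stop(sprintf("%s values outside [0, 1]", what))
    unname(S)
  }
  dimnames(RD) <- list(rna_ids, disease_ids)
  obj <- list(
    rna_ids = as.character(rna_ids),
    disease_ids = as.character(disease_ids),
    RD = RD,
    SR = check_sim(SR, nrow(RD), "SR"),
    SD = check_sim(SD, ncol(RD), "SD")
  )
  class(obj) <- "association_dataset"
  obj
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf(
    "association_dataset: %d ncRNAs x %d diseases, %d links (density %.4f)\n",
    length(x$rna_ids), length(x$disease_ids), sum(x$RD), dataset_density(x)))
  cat(sprintf("  similarities: SR %s, SD %s\n",
              if (is.null(x$SR)) "absent" else "present",
              if (is.null(x$SD)) "absent" else "present"))
  invisible(x)
}

#' Association density of a dataset
#'
#' The fraction of observed links among all ncRNA-disease pairs,
#' `sum(RD) / (r * d)` — the sparseness statistic usually quoted for
#' association benchmarks.
#'
#' @param x an `association_dataset`, or a count of links if `r`/`d` given.
#' @param r,d node counts, used when `x` is a plain link count.
#' @return numeric density in `[0, 1]`.
#' @export
dataset_density <- function(x, r = NULL, d = NULL) {
  if (inherits(x, "association_dataset")) {
    sum(x$RD) / (length(x$rna_ids) * length(x$disease_ids))
  } else {
    stopifnot(is.numeric(x), !is.null(r), !is.null(d))
    x / (r * d)
  }
}

#' Specification for the synthetic block-structured benchmark
#'
#' The generator emulates the sparse bipartite association matrices of real
#' ncRNA-disease benchmarks (density roughly 0.01-0.09) by planting latent
#' groups: ncRNAs and diseases are assigned uniformly at random to
#' `n_blocks` groups, a link appears with probability `p_intra` when the two
#' groups match and `p_inter` otherwise, and similarity matrices equal the
#' same-group indicator plus Gaussian noise. The defaults are the conditions
#' used throughout the package's own validation experiments.
#'
#' @param r,d numbers of ncRNAs and diseases.
#' @param n_blocks number of latent groups.
#' @param p_intra,p_inter link probabilities within/between matched groups;
#'   `0 <= p_inter <= p_intra <= 1`.
#' @param sim_noise standard deviation of the additive similarity noise.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(r = 200, d = 100, n_blocks = 4, p_intra = 0.2,
                           p_inter = 0.005, sim_noise = 0.1, seed = 0) {
  stopifnot(r >= 1, d >= 1, n_blocks >= 1, sim_noise >= 0,
            p_inter >= 0, p_intra <= 1, p_inter <= p_intra)
  structure(list(r = r, d = d, n_blocks = n_blocks, p_intra = p_intra,
                 p_inter = p_inter, sim_noise = sim_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic block-structured association dataset
#'
#' @param spec a [synthetic_spec()].
#' @return an `association_dataset` with attributes `rna_groups` and
#'   `disease_groups` recording the planted group memberships.
#' @seealso [synthetic_spec()] for the generative model.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  draw <- function() {
    rg <- sample.int(spec$n_blocks, spec$r, replace = TRUE)
    dg <- sample.int(spec$n_blocks, spec$d, replace = TRUE)
    same <- outer(rg, dg, "==")
    p <- ifelse(same, spec$p_intra, spec$p_inter)
    RD <- matrix(as.numeric(stats::runif(spec$r * spec$d) <
                              as.vector(p)), spec$r, spec$d)
    list(rg = rg, dg = dg, RD = RD)
  }
  sim_from_groups <- function(groups, noise_sd) {
    S <- outer(groups, groups, function(a, b) as.numeric(a == b))
    n <- length(groups)
    if (noise_sd > 0) S <- S + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
    S <- (S + t(S)) / 2
    S <- pmin(pmax(S, 0), 1)
    diag(S) <- 1
    S
  }
  withr::with_seed(spec$seed, {
    g <- draw()
    if (sum(g$RD) == 0) g <- draw()
    if (sum(g$RD) == 0) stop("synthetic spec produced zero associations")
    SR <- sim_from_groups(g$rg, spec$sim_noise)
    SD <- sim_from_groups(g$dg, spec$sim_noise)
    ds <- association_dataset(g$RD,
                              rna_ids = paste0("R", seq_len(spec$r)),
                              disease_ids = paste0("D", seq_len(spec$d)),
                              SR = SR, SD = SD)
    attr(ds, "rna_groups") <- g$rg
    attr(ds, "disease_groups") <- g$dg
    ds
  })
}

#' Replace the association matrix by an equally dense random one
#'
#' Permutes the entries of `RD` uniformly at random, destroying any relation
#' between links and the similarity structure while keeping the exact link
#' count. Used as the null control in the validation experiments.
#'
#' @param dataset an `association_dataset`.
#' @param seed integer seed.
#' @return the dataset with shuffled `RD`.
#' @export
shuffle_associations <- function(dataset, seed = 0) {
  stopifnot(inherits(dataset, "association_dataset"))
  RD <- dataset$RD
  withr::with_seed(as.integer(seed), {
    RD[] <- sample(as.vector(RD))
  })
  dataset$RD <- RD
  dataset
}

#' Read an association matrix from a text file
#'
#' Two layouts are supported. `edge_list`: a headerless 2- or 3-column TSV of
#' `rna_id  disease_id  [weight]` rows; any positive weight becomes a link
#' and node order follows first appearance. `matrix`: a dense TSV whose first
#' row and first column hold the disease and ncRNA labels.
#'
#' @param path file path.
#' @param format `"edge_list"` or `"matrix"`.
#' @param sr_path,sd_path optional paths to similarity matrices (see
#'   [read_similarity()]); their labels must match the association labels.
#' @return an `association_dataset`.
#' @export
read_association <- function(path, format = c("edge_list", "matrix"),
                             sr_path = NULL, sd_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edge_list") {
    tab <- tryCatch(
      utils::read.delim(path, header = FALSE, sep = "\t",
                        colClasses = "character", blank.lines.skip = TRUE),
      error = function(e) stop("no associations in ", path))
    if (nrow(tab) == 0) stop("no associations in ", path)
    if (ncol(tab) < 2) stop("edge list needs at least 2 columns")
    w <- if (ncol(tab) >= 3) as.numeric(tab[[3]]) else rep(1, nrow(tab))
    keep <- w > 0
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) == 0) stop("no associations in ", path)
    key <- paste(tab[[1]], tab[[2]], sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate edges deduplicated: ",
              sum(duplicated(key)), " duplicates")
      tab <- tab[!duplicated(key), , drop = FALSE]
    }
    rna_ids <- unique(tab[[1]])
    disease_ids <- unique(tab[[2]])
    RD <- matrix(0, length(rna_ids), length(disease_ids),
                 dimnames = list(rna_ids, disease_ids))
    RD[cbind(match(tab[[1]], rna_ids), match(tab[[2]], disease_ids))] <- 1
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                             check.names = FALSE)
    RD <- as.matrix(tab)
    if (nrow(RD) == 0 || sum(RD) == 0) stop("no associations in ", path)
    RD[RD > 0] <- 1
    rna_ids <- rownames(RD)
    disease_ids <- colnames(RD)
  }
  match_sim <- function(sp, ids, what) {
    if (is.null(sp)) return(NULL)
    S <- read_similarity(sp)
    lab <- rownames(S)
    missing <- setdiff(ids, lab)
    extra <- setdiff(lab, ids)
    if (length(missing) > 0 || length(extra) > 0) {
      bad <- c(extra, missing)[1]
      stop(sprintf("%s label '%s' does not match the association labels",
                   what, bad))
    }
    S[ids, ids]
  }
  association_dataset(RD, rna_ids, disease_ids,
                      SR = match_sim(sr_path, rna_ids, "SR"),
                      SD = match_sim(sd_path, disease_ids, "SD"))
}

#' Read a similarity matrix from a labelled TSV file
#'
#' Real similarity files distributed with association benchmarks are noisy:
#' values slightly outside `[0, 1]` are clipped, asymmetries beyond `1e-8`
#' are repaired as `(S + t(S)) / 2`, and the diagonal is set to 1 — each
#' repair with a warning. A non-square matrix is an error.
#'
#' @param path TSV file with labels in the first row and first column.
#' @return a numeric labelled square matrix in `[0, 1]`.
#' @export
read_similarity <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  S <- as.matrix(tab)
  if (nrow(S) != ncol(S)) {
    stop(sprintf("similarity matrix is not square: %d x %d",
                 nrow(S), ncol(S)))
  }
  storage.mode(S) <- "double"
  if (anyNA(S)) stop("similarity matrix contains unparseable values")
  if (min(S) < 0 || max(S) > 1) {
    warning("similarity values outside [0, 1] clipped")
    S <- pmin(pmax(S, 0), 1)
  }
  if (max(abs(S - t(S))) > 1e-8) {
    warning("similarity matrix symmetrized as (S + t(S)) / 2")
    S <- (S + t(S)) / 2
  }
  if (any(abs(diag(S) - 1) > 1e-8)) diag(S) <- 1
  S
}

#' Write pair scores as a TSV file
#'
#' Rows are sorted by descending score; columns are `rna_id`, `disease_id`,
#' `score`. An empty input yields a header-only file.
#'
#' @param pairs data frame with columns `rna_id`, `disease_id`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(pairs, path) {
  stopifnot(all(c("rna_id", "disease_id", "score") %in% names(pairs)))
  pairs <- pairs[order(-pairs$score), c("rna_id", "disease_id", "score")]
  ok <- tryCatch({
    utils::write.table(format(pairs, digits = 15, scientific = FALSE,
                              trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write scores to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "numeric"))
  names(tab) <- c("rna_id", "disease_id", "score")
  tab
}

#' Write / read a flat metrics report
#'
#' Metrics are serialized as a flat JSON object of key-value pairs with full
#' double precision, so a round trip reproduces the values exactly.
#'
#' @param report named list or named numeric vector of metric values.
#' @param path output path.
#' @return `path` invisibly (`write_metrics`); named list (`read_metrics`).
#' @export
write_metrics <- function(report, path) {
  report <- as.list(report)
  stopifnot(length(names(report)) == length(report))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
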