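## Consensus gene-set construction from per-experiment differential tables,
## ortholog mapping, and GMT input/output. The nine production sets are the
## up/down consensus sets for stress response (SR), wound healing (WH) and
## regeneration (RG) plus three direction-agnostic human-database sets
## (SR-H, WH-H, RG-H).

PROCESSES <- c("SR", "WH", "RG", "other")
DIRECTIONS <- c("UP", "DOWN", "AGNOSTIC")

#' Construct a gene set
#'
#' @param name set name, unique within a collection.
#' @param members character vector of gene identifiers.
#' @param process one of `"SR"`, `"WH"`, `"RG"`, `"other"`.
#' @param direction one of `"UP"`, `"DOWN"`, `"AGNOSTIC"`.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, members, process = "other", direction = "AGNOSTIC") {
  process <- match.arg(process, PROCESSES)
  direction <- match.arg(direction, DIRECTIONS)
  structure(
    list(name = as.character(name),
         process = process,
         direction = direction,
         members = sort(unique(as.character(members)))),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s|%s], %d member(s)\n",
              x$name, x$process, x$direction, length(x$members)))
  invisible(x)
}

#' Construct an ordered gene-set collection
#'
#' Order is fixed and defines the feature-column order downstream.
#'
#' @param sets list of [gene_set()] objects with unique names.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  stopifnot(is.list(sets), all(vapply(sets, inherits, TRUE, "gene_set")))
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate gene-set name(s): %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  names(sets) <- nm
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d set(s): %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Filter a differential table to significant genes in one direction
#'
#' Keeps genes with adjusted p-value strictly below `alpha` and log2
#' fold-change at or beyond `min_abs_lfc` in the requested direction
#' (`log_fc >= min_abs_lfc` for UP, `log_fc <= -min_abs_lfc` for DOWN).
#' Defaults reproduce the conventional differential-expression call:
#' adjusted p < 0.05 and |LFC| >= 1. Duplicate gene rows collapse to one
#' membership.
#'
#' @param records data.frame with columns `gene`, `log_fc`, `adj_p`.
#' @param direction `"UP"` or `"DOWN"`.
#' @param alpha significance level in (0, 1\]; strict inequality.
#' @param min_abs_lfc minimum absolute log2 fold-change; inclusive.
#' @param name name for the resulting set.
#' @param process process tag for the resulting set.
#' @return a [gene_set()].
#' @export
filter_significant <- function(records, direction = c("UP", "DOWN"),
                               alpha = 0.05, min_abs_lfc = 1,
                               name = NULL, process = "other") {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(records),
            all(c("gene", "log_fc", "adj_p") %in% names(records)),
            alpha > 0, alpha <= 1, min_abs_lfc >= 0)
  if (any(records$adj_p < 0 | records$adj_p > 1, na.rm = TRUE)) {
    stop("adj_p values must lie in [0, 1]")
  }
  sig <- !is.na(records$adj_p) & records$adj_p < alpha
  keep <- if (direction == "UP") {
    sig & records$log_fc >= min_abs_lfc
  } else {
    sig & records$log_fc <= -min_abs_lfc
  }
  gene_set(name %||% direction, records$gene[keep],
           process = process, direction = direction)
}

#' Map genes to human orthologs through a lookup table
#'
#' Replaces each source-species gene by all of its mapped human genes
#' (one-to-many mappings contribute every target; many-to-one collapse).
#' Genes without a human ortholog are excluded, with a logged count.
#'
#' @param genes character vector of source genes.
#' @param mapping data.frame with columns `source`, `human`.
#' @return character vector of human genes (sorted, unique).
#' @export
map_orthologs <- function(genes, mapping) {
  stopifnot(is.data.frame(mapping), all(c("source", "human") %in% names(mapping)))
  genes <- unique(as.character(genes))
  hit <- mapping$source %in% genes
  n_unmapped <- sum(!genes %in% mapping$source)
  if (n_unmapped > 0) {
    dp_log("%d gene(s) without a human ortholog were excluded", n_unmapped)
  }
  sort(unique(as.character(mapping$human[hit])))
}

#' Build a consensus gene set across datasets
#'
#' Keeps genes represented in at least `min_datasets` of the supplied
#' per-dataset gene sets (the default of 2 is the "at least two separate
#' datasets" consensus rule). Inputs must already be collapsed to dataset
#' level: multiple experiments within one dataset are unioned per direction
#' before counting, so that no single multi-experiment dataset can dominate
#' the consensus.
#'
#' @param per_dataset_sets list of character vectors (or `gene_set`s), one
#'   per dataset.
#' @param min_datasets minimum number of datasets a gene must appear in.
#' @param name,process,direction metadata for the resulting set.
#' @return a [gene_set()].
#' @export
build_consensus <- function(per_dataset_sets, min_datasets = 2,
                            name = "consensus", process = "other",
                            direction = "AGNOSTIC") {
  stopifnot(min_datasets >= 1)
  members_of <- function(s) if (inherits(s, "gene_set")) s$members else unique(as.character(s))
  sets <- lapply(per_dataset_sets, members_of)
  if (length(sets) < min_datasets) {
    warning(sprintf("only %d dataset(s) supplied but min_datasets = %d; consensus is empty",
                    length(sets), min_datasets))
    return(gene_set(name, character(0), process, direction))
  }
  counts <- table(unlist(sets, use.names = FALSE))
  gene_set(name, names(counts)[counts >= min_datasets], process, direction)
}

## Encode/decode the "process|direction" metadata carried in the GMT
## description field; AGNOSTIC when absent or unrecognized.
.encode_meta <- function(set) paste(set$process, set$direction, sep = "|")
.decode_meta <- function(desc) {
  parts <- strsplit(desc, "|", fixed = TRUE)[[1]]
  process <- if (length(parts) >= 1 && parts[1] %in% PROCESSES) parts[1] else "other"
  direction <- if (length(parts) >= 2 && parts[2] %in% DIRECTIONS) parts[2] else "AGNOSTIC"
  list(process = process, direction = direction)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT lines are `name TAB description TAB gene1 TAB gene2 ...`. The
#' description field may carry `process|direction` metadata (e.g. `SR|UP`);
#' sets without it are treated as direction-agnostic.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("GMT file '%s' is empty", path))
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT line %d: set '%s' has an empty member list", i, f[1]))
    }
    meta <- .decode_meta(f[2])
    gene_set(f[1], f[-(1:2)], process = meta$process, direction = meta$direction)
  })
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate set name '%s' in GMT file", nm[duplicated(nm)][1]))
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection to a GMT file
#'
#' Round-trips with [read_gmt()]: names, order, members and the
#' `process|direction` metadata are all preserved.
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection, function(s) {
    if (length(s$members) == 0) {
      stop(sprintf("set '%s' has no members; refusing to write an empty GMT record", s$name))
    }
    paste(c(s$name, .encode_meta(s), s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table (TSV: gene, log_fc, adj_p)
#'
#' @param path TSV path with a header line.
#' @return data.frame with columns `gene`, `log_fc`, `adj_p`.
#' @export
read_differential <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "log_fc", "adj_p")
  if (!all(need %in% names(df))) {
    stop(sprintf("differential table '%s' must have columns: %s",
                 path, paste(need, collapse = ", ")))
  }
  df[need]
}

#' Read an ortholog mapping table (TSV: source, human)
#'
#' @param path TSV path with a header line.
#' @return data.frame with columns `source`, `human`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("source", "human") %in% names(df))) {
    stop(sprintf("ortholog map '%s' must have columns: source, human", path))
  }
  df[c("source", "human")]
}

#' Read a plain gene list (one gene per line)
#'
#' @param path file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
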