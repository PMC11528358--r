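# Plain-text readers and writers for the pipeline's tables: per-group-year
# observation directories, posterior edge lists and centrality/result
# tables. All files are tab-separated with headers.

#' Write a group-year observation set to a directory
#'
#' Writes `individuals.tsv` (id, age, focal_count) and `dyads.tsv`
#' (id_a, id_b, bouts) into `dir`.
#'
#' @param obs a `group_year_obs` object.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_group_year <- function(obs, dir) {
  stopifnot(inherits(obs, "group_year_obs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(obs$individuals, file.path(dir, "individuals.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(obs$dyads, file.path(dir, "dyads.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a group-year observation set from a directory
#'
#' Reads the tables written by [write_group_year()] (or user-supplied
#' tables in the same layout) and validates them: unique ids, positive
#' focal counts, dyads referencing known distinct ids, non-negative bouts.
#'
#' @param dir directory containing `individuals.tsv` and `dyads.tsv`.
#' @param label group-year label; default is the directory basename.
#' @return A `group_year_obs` object.
#' @export
read_group_year <- function(dir, label = basename(normalizePath(dir))) {
  ind <- read.table(file.path(dir, "individuals.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  dy <- read.table(file.path(dir, "dyads.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("id", "age", "focal_count") %in% names(ind)))
    stop("individuals.tsv must have columns id, age, focal_count")
  if (!all(c("id_a", "id_b", "bouts") %in% names(dy)))
    stop("dyads.tsv must have columns id_a, id_b, bouts")
  if (anyDuplicated(ind$id)) stop("duplicate individual ids")
  if (any(ind$focal_count < 1)) stop("focal counts must be >= 1")
  if (any(dy$bouts < 0)) stop("bout counts must be >= 0")
  if (any(dy$id_a == dy$id_b)) stop("self-dyads are not allowed")
  unknown <- setdiff(c(dy$id_a, dy$id_b), ind$id)
  if (length(unknown))
    stop("dyads reference unknown ids: ", paste(unknown, collapse = ", "))
  structure(list(label = label, individuals = ind, dyads = dy),
            class = "group_year_obs")
}

#' Write a generator configuration as key-value text
#'
#' @param config a [gen_config()] object.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_gen_config <- function(config, file) {
  stopifnot(inherits(config, "gen_config"))
  vals <- vapply(unclass(config), function(v) paste(v, collapse = ","),
                 character(1))
  writeLines(paste(names(vals), vals, sep = " = "), file)
  invisible(file)
}

#' Read a generator configuration from key-value text
#'
#' @param file a file written by [write_gen_config()].
#' @return A [gen_config()] object.
#' @export
read_gen_config <- function(file) {
  lines <- readLines(file)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- lapply(kv, function(p) as.numeric(strsplit(p[2], ",")[[1]]))
  names(vals) <- vapply(kv, `[`, character(1), 1)
  do.call(gen_config, vals)
}

#' Export posterior network draws as a long edge list
#'
#' Writes (or returns) one row per dyad per draw:
#' `group_year, draw, id_a, id_b, weight`.
#'
#' @param networks list of `posterior_network` draws.
#' @param file optional output path (tab-separated).
#' @return The edge-list data.frame (invisibly if written to `file`).
#' @export
write_networks <- function(networks, file = NULL) {
  if (inherits(networks, "posterior_network")) networks <- list(networks)
  rows <- lapply(networks, function(net) {
    ut <- which(upper.tri(net$weights), arr.ind = TRUE)
    data.frame(group_year = net$group_year, draw = net$draw,
               id_a = net$ids[ut[, 1]], id_b = net$ids[ut[, 2]],
               weight = net$weights[ut], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(file)) {
    write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
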