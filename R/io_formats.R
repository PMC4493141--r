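# Line-oriented TSV/JSON export and import of networks, decompositions,
# profiles and maps.

#' Write a constraint network to TSV
#'
#' One constraint per line: `body_a`, `body_b`, `kind`, `bars`, `energy`.
#'
#' @param net a `cna_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "cna_network"))
  write.table(net$constraints, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a constraint network from TSV
#'
#' The inverse of [write_network()]. The resulting network carries no
#' structure reference; generic coordinates are attached so the rank oracle
#' remains usable on small instances.
#'
#' @param path TSV file written by [write_network()].
#' @param n_bodies number of bodies; defaults to the largest endpoint id.
#' @return a `cna_network`.
#' @export
read_network <- function(path, n_bodies = NULL) {
  con <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(n_bodies)) n_bodies <- max(con$body_a, con$body_b)
  make_toy_network(n_bodies, con)
}

#' Write a network as JSON
#' @inheritParams write_network
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "cna_network"))
  jsonlite::write_json(list(n_bodies = net$n_bodies,
                            constraints = net$constraints),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a rigid cluster decomposition to TSV
#'
#' One body per line with its cluster label (clusters ranked by size).
#'
#' @param d a `cna_decomposition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(d, path) {
  stopifnot(inherits(d, "cna_decomposition"))
  write.table(data.frame(body = seq_len(d$n_bodies),
                         cluster = d$cluster_id,
                         cluster_size = d$sizes[d$cluster_id]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an unfolding trajectory to a directory
#'
#' Emits the per-state summary TSV and one decomposition TSV per distinct
#' state.
#'
#' @param traj a `cna_trajectory`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "cna_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(traj$summary, file.path(dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(traj$ladder))) {
    write_decomposition(traj$decompositions[[i]],
                        file.path(dir, sprintf("state_%03d.tsv", i)))
  }
  invisible(dir)
}

#' Write a residue-wise profile to TSV
#' @param profile a `cna_profile` (or data frame with `residue_index`, `p_i`).
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  write.table(profile[, c("residue_index", "p_i")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a residue-by-residue matrix to TSV
#' @param m matrix (e.g. a stability map's `rc` or a difference map).
#' @param path output path.
#' @export
write_matrix <- function(m, path) {
  write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
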