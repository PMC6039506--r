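# Decimal output uses 17 significant digits so every written table
# round-trips bit-exactly through read.table.
fmt17 <- function(x) sprintf("%.17g", x)

header_lines <- function(params) {
  if (length(params) == 0L) return(character(0))
  vals <- vapply(params, function(v) paste(format(v, digits = 17),
                                           collapse = ","), character(1))
  paste0("# ", names(params), "=", vals)
}

#' Write / read a discrete distribution as TSV
#'
#' Two tab-separated columns (`T`, `P`) preceded by `#`-prefixed header
#' lines recording the generating parameters and the package version.
#' Probabilities are written with 17 significant digits so the file
#' re-parses into the identical distribution.
#'
#' @param dist a [discrete_dist()].
#' @param path output file.
#' @param params named list recorded in the header.
#' @export
write_distribution <- function(dist, path, params = list()) {
  sup <- dist_support(dist)
  lines <- c(header_lines(c(list(package = paste0("seqnoise ",
               as.character(utils::packageVersion("seqnoise")))), params)),
             "T\tP",
             paste(sup, fmt17(dist$probs), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  stopifnot(all(diff(tab$T) == 1))
  discrete_dist(tab$T[1], tab$P)
}

#' Write / read a joint distribution as long-format TSV
#'
#' Columns named after the two axes plus `P`, one row per grid cell
#' (including exact zeros, so the rectangle is reconstructed unambiguously).
#'
#' @param joint a [joint_dist()].
#' @param path output file.
#' @param params named list recorded in the header.
#' @export
write_joint <- function(joint, path, params = list()) {
  v1 <- joint$o1 + seq_len(nrow(joint$p)) - 1L
  v2 <- joint$o2 + seq_len(ncol(joint$p)) - 1L
  g <- expand.grid(a = v1, b = v2)
  lines <- c(header_lines(c(list(package = paste0("seqnoise ",
               as.character(utils::packageVersion("seqnoise")))), params)),
             paste(joint$axes[1], joint$axes[2], "P", sep = "\t"),
             paste(g$a, g$b, fmt17(as.vector(joint$p)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_joint
#' @export
read_joint <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  axes <- colnames(tab)[1:2]
  v1 <- sort(unique(tab[[1]]))
  v2 <- sort(unique(tab[[2]]))
  p <- matrix(0, length(v1), length(v2))
  p[cbind(match(tab[[1]], v1), match(tab[[2]], v2))] <- tab$P
  joint_dist(v1[1], v2[1], p, axes = axes)
}

#' Write a summary JSON for a distribution
#'
#' Flat JSON object with mean, variance, mode count and support bounds.
#'
#' @param dist a [discrete_dist()].
#' @param path output file.
#' @param extra named list merged into the object.
#' @export
write_summary_json <- function(dist, path, extra = list()) {
  jsonlite::write_json(c(dist_summary(dist), extra), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a bimodality scan as long-format TSV plus a JSON boundary summary
#'
#' One row per grid node with columns `T_T`, `sigma`, `CV`
#' (`sigma / mean_ST`) and `n_modes`; the companion JSON file records the
#' bimodal-region node count and its boundary nodes.
#'
#' @param scan a [bimodality_scan()] result.
#' @param path TSV output file; the JSON summary goes to
#'   `paste0(path, ".json")` unless `json_path` is given.
#' @param json_path optional explicit JSON path.
#' @export
write_scan <- function(scan, path, json_path = paste0(path, ".json")) {
  g <- expand.grid(T_T = scan$T_T, sigma = scan$sigma)
  g$CV <- g$sigma / scan$mean_ST
  g$n_modes <- as.vector(scan$modes)
  lines <- c(header_lines(list(model = scan$model, mean_ST = scan$mean_ST,
                               K_d = scan$K_d,
                               a = if (is.null(scan$a)) NA else scan$a)),
             "T_T\tsigma\tCV\tn_modes",
             paste(g$T_T, fmt17(g$sigma), fmt17(g$CV), g$n_modes,
                   sep = "\t"))
  writeLines(lines, path)
  jsonlite::write_json(
    list(model = scan$model, area = scan$area,
         boundary = scan$boundary),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a sweep table (correlation / mutual information / locus) as TSV
#'
#' @param table data frame from one of the sweep drivers.
#' @param path output file.
#' @param params named list recorded in the header.
#' @export
write_sweep <- function(table, path, params = list()) {
  num <- vapply(table, is.double, logical(1))
  tab <- table
  tab[num] <- lapply(tab[num], fmt17)
  lines <- c(header_lines(c(list(package = paste0("seqnoise ",
               as.character(utils::packageVersion("seqnoise")))), params)),
             paste(colnames(tab), collapse = "\t"),
             do.call(paste, c(unname(tab), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
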