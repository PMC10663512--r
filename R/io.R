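# File formats: edge lists and coordinate tables.

#' Read an undirected edge list
#'
#' Parses a plain-text edge list (two whitespace-separated node labels per
#' line, '#' comment lines allowed), drops self-loops and duplicate edges
#' (with a message reporting the counts), and keeps the largest connected
#' component (with a warning listing how many nodes were discarded).
#' Original labels are kept as vertex names.
#'
#' @param path file path.
#' @return A simple, connected igraph object.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("empty edge list: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad))
    stop(sprintf("malformed edge list line %d: '%s'", rows[bad[1L]],
                 lines[rows[bad[1L]]]), call. = FALSE)
  el <- do.call(rbind, toks)
  loops <- el[, 1L] == el[, 2L]
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  el <- el[!loops, , drop = FALSE]
  if (!nrow(el)) stop("no edges left after dropping self-loops", call. = FALSE)
  key <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  dup <- duplicated(key)
  if (any(dup)) message(sum(dup), " duplicate edge(s) collapsed")
  el <- el[!dup, , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    keep_c <- which.max(comp$csize)
    warning(sprintf(
      "graph is disconnected: keeping the largest component (%d nodes), discarding %d node(s) in %d smaller component(s)",
      comp$csize[keep_c], sum(comp$csize[-keep_c]), comp$no - 1L))
    g <- igraph::induced_subgraph(g, which(comp$membership == keep_c))
  }
  g
}

#' Write embedding coordinates to a TSV table
#'
#' Writes one row per node — label, hidden degree kappa, the D+1 similarity
#' components (unit vector) and the hyperbolic radius r — preceded by
#' '# key=value' comment lines carrying N, D, beta, mu, R and R_hat. All
#' numbers are printed with 17 significant digits so a read-back reproduces
#' them bit-identically.
#'
#' @param embedding an `sd_embedding`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(embedding, path) {
  p <- embedding$params
  hyp <- to_hyperbolic(embedding)
  D <- p$D
  hdr <- c(sprintf("# N=%d", p$N), sprintf("# D=%d", D),
           sprintf("# beta=%.17g", p$beta), sprintf("# mu=%.17g", p$mu),
           sprintf("# R=%.17g", p$R), sprintf("# R_hat=%.17g", hyp$R_hat))
  cols <- c("label", "kappa", paste0("v", seq_len(D + 1L)), "r")
  num <- cbind(embedding$kappa, embedding$positions, hyp$radial)
  body <- apply(num, 1L, function(x) paste(sprintf("%.17g", x), collapse = "\t"))
  labels <- embedding$labels
  if (is.null(labels)) labels <- as.character(seq_len(p$N))
  writeLines(c(hdr, paste(cols, collapse = "\t"),
               paste(labels, body, sep = "\t")), path)
  invisible(path)
}

#' Read a coordinate table written by [write_coordinates]
#'
#' Validates the header against the column layout (the declared D must match
#' the number of similarity components; the kappa column must be present)
#' and checks that stored vectors are unit-norm.
#'
#' @param path file path.
#' @return A list of class `sd_coordinates`: `labels`, `kappa`, unit-row
#'   `positions`, `radial`, and the header fields `N`, `D`, `beta`, `mu`,
#'   `R`, `R_hat`.
#' @export
read_coordinates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr_lines, regexec("^#\\s*([A-Za-z_]+)=(.*)$", hdr_lines))
  hdr <- list()
  for (m in kv) if (length(m) == 3L) hdr[[m[2L]]] <- as.numeric(m[3L])
  for (need in c("N", "D", "beta", "mu", "R", "R_hat"))
    if (is.null(hdr[[need]]))
      stop("coordinate table header is missing ", need, call. = FALSE)
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t", colClasses = "character")
  D <- as.integer(hdr$D)
  vcols <- paste0("v", seq_len(D + 1L))
  if (!("kappa" %in% names(tab)))
    stop("coordinate table is missing the 'kappa' column", call. = FALSE)
  if (!all(vcols %in% names(tab)) ||
      length(grep("^v[0-9]+$", names(tab))) != D + 1L)
    stop(sprintf(
      "header D=%d disagrees with the similarity columns present (%s)",
      D, paste(grep("^v[0-9]+$", names(tab), value = TRUE), collapse = ", ")),
      call. = FALSE)
  if (!("r" %in% names(tab)))
    stop("coordinate table is missing the 'r' column", call. = FALSE)
  pos <- as.matrix(vapply(tab[vcols], as.numeric, numeric(nrow(tab))))
  dim(pos) <- c(nrow(tab), D + 1L)
  if (nrow(pos) != hdr$N)
    stop(sprintf("header N=%d but %d rows found", as.integer(hdr$N),
                 nrow(pos)), call. = FALSE)
  nrm <- sqrt(rowSums(pos^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("stored similarity vectors are not unit norm", call. = FALSE)
  structure(list(labels = tab$label, kappa = as.numeric(tab$kappa),
                 positions = pos, radial = as.numeric(tab$r),
                 N = as.integer(hdr$N), D = D, beta = hdr$beta,
                 mu = hdr$mu, R = hdr$R, R_hat = hdr$R_hat),
            class = "sd_coordinates")
}
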