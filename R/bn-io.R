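#' Serialize a network to JSON
#'
#' Document layout: `{"nodes": [{"name", "states"}], "edges": [{"from",
#' "to"}], "cpts": {node: {"<parent_config>": [probs...]}}}` where
#' `<parent_config>` joins parent states with `"/"` in the DAG's parent
#' order (`"."` for root nodes). The round trip through
#' [bn_from_json()] is exact.
#'
#' @param bn An [fit_cpts()] network.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
bn_to_json <- function(bn, path) {
  nodes <- lapply(names(bn$dag$nodes), function(n) {
    list(name = n, states = bn$dag$nodes[[n]])
  })
  e <- dag_edges(bn$dag)
  edges <- lapply(seq_len(nrow(e)), function(i) as.list(e[i, ]))
  cpts <- list()
  for (n in names(bn$cpts)) {
    parents <- bn$dag$parents[[n]]
    cpt <- bn$cpts[[n]]
    entry <- list()
    if (length(parents) == 0) {
      entry[["."]] <- as.numeric(cpt)
    } else {
      cfgs <- expand.grid(bn$dag$nodes[parents], stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      for (i in seq_len(nrow(cfgs))) {
        idx <- c(list(seq_along(bn$dag$nodes[[n]])),
                 lapply(parents, function(p) {
                   match(cfgs[i, p], bn$dag$nodes[[p]])
                 }))
        entry[[paste(unlist(cfgs[i, ]), collapse = "/")]] <-
          as.numeric(do.call(`[`, c(list(cpt), idx)))
      }
    }
    cpts[[n]] <- entry
  }
  # I(17) significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(list(nodes = nodes, edges = edges, cpts = cpts), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Deserialize a network from JSON
#'
#' @param path Path written by [bn_to_json()].
#' @return An `or_bn`.
#' @export
bn_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  states <- list()
  for (nd in doc$nodes) states[[nd$name]] <- unlist(nd$states)
  dag <- dag_new(states,
                 lapply(doc$edges, function(e) c(e$from, e$to)))
  cpts <- list()
  for (n in names(doc$cpts)) {
    parents <- dag$parents[[n]]
    r <- length(states[[n]])
    if (length(parents) == 0) {
      cpt <- array(unlist(doc$cpts[[n]][["."]]), dim = r,
                   dimnames = setNames(list(states[[n]]), n))
    } else {
      dims <- unname(c(r, vapply(states[parents], length, 1L)))
      cpt <- array(NA_real_, dim = dims,
                   dimnames = c(setNames(list(states[[n]]), n), states[parents]))
      cfgs <- expand.grid(states[parents], stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      for (i in seq_len(nrow(cfgs))) {
        key <- paste(unlist(cfgs[i, ]), collapse = "/")
        idx <- c(list(seq_len(r)),
                 lapply(parents, function(p) match(cfgs[i, p], states[[p]])))
        cpt <- do.call(`[<-`, c(list(cpt), idx,
                                list(unlist(doc$cpts[[n]][[key]]))))
      }
    }
    cpts[[n]] <- cpt
  }
  structure(list(dag = dag, cpts = cpts), class = "or_bn")
}
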