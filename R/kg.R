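RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
XSD_NS <- "http://www.w3.org/2001/XMLSchema#"

#' Vocabulary for the observation knowledge graph
#'
#' IRIs of the Forest Observatory Ontology (FOO) and W3C WGS84 geo terms
#' used by the graph: observation class, coordinate/date/time properties,
#' the poaching flag, the plantation node and class, plus configurable
#' sensor and feature-of-interest link predicates (the ontology requires
#' the links but fixes no predicate spelling, so they are configuration).
#' External entities are attached to the namespace as `#` fragments.
#'
#' @param foo_ns,wgs84_ns,ext_ns namespace IRIs; `ext_ns` holds provenance
#'   terms for model-generated observations.
#' @param sensor_link,foi_link predicate IRIs linking an observation to its
#'   sensor and feature of interest.
#' @return a list of class `"kg_vocabulary"` with absolute term IRIs.
#' @export
foo_vocabulary <- function(foo_ns = "https://w3id.org/def/foo#",
                           wgs84_ns = "http://www.w3.org/2003/01/geo/wgs84_pos#",
                           ext_ns = "https://w3id.org/def/foo/ext#",
                           sensor_link = NULL,
                           foi_link = NULL) {
  v <- list(
    foo_ns = foo_ns, wgs84_ns = wgs84_ns, ext_ns = ext_ns,
    class_observation = paste0(foo_ns, "gPSObservation"),
    class_plantation = paste0(foo_ns, "OilPalmPlantation"),
    class_sensor = paste0(foo_ns, "GPS"),
    class_animal = paste0(foo_ns, "Elephant"),
    p_lat = paste0(wgs84_ns, "latitude"),
    p_lon = paste0(wgs84_ns, "longitude"),
    p_date = paste0(foo_ns, "localDate"),
    p_time = paste0(foo_ns, "localTime"),
    p_poaching = paste0(foo_ns, "poaching"),
    plantation_node = paste0(foo_ns, "plantation"),
    sensor_node = paste0(foo_ns, "collar_gps"),
    foi_node = paste0(foo_ns, "elephant"),
    sensor_link = sensor_link %||% paste0(foo_ns, "observedBy"),
    foi_link = foi_link %||% paste0(foo_ns, "featureOfInterest"),
    p_predicted_by = paste0(ext_ns, "predictedBy"),
    model_node = paste0(ext_ns, "geoLocationModel"),
    xsd_float = paste0(XSD_NS, "float"),
    xsd_date = paste0(XSD_NS, "date"),
    xsd_time = paste0(XSD_NS, "time"),
    xsd_integer = paste0(XSD_NS, "integer")
  )
  structure(v, class = "kg_vocabulary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create an empty triple graph
#'
#' A triple graph is a tibble with one row per RDF triple and columns
#' `subject`, `predicate`, `object`, `object_type` (`"iri"` or
#' `"literal"`) and `datatype` (datatype IRI, `NA` for IRIs and plain
#' literals).  The table is kept duplicate-free.
#'
#' @return an empty triple-graph tibble of class `"triple_graph"`.
#' @export
triple_graph <- function() {
  g <- tibble::tibble(subject = character(), predicate = character(),
                      object = character(), object_type = character(),
                      datatype = character())
  class(g) <- c("triple_graph", class(g))
  g
}

as_triple_graph <- function(df) {
  g <- dplyr::distinct(tibble::as_tibble(df))
  class(g) <- unique(c("triple_graph", class(g)))
  g
}

tg_rows <- function(subject, predicate, object, object_type, datatype = NA_character_) {
  tibble::tibble(subject = subject, predicate = predicate, object = object,
                 object_type = object_type, datatype = datatype)
}

#' Set equality of two triple graphs
#'
#' @param g1,g2 triple-graph tibbles.
#' @return `TRUE` when both contain exactly the same set of triples.
#' @export
graph_equal <- function(g1, g2) {
  cols <- c("subject", "predicate", "object", "object_type", "datatype")
  a <- dplyr::arrange(dplyr::distinct(tibble::as_tibble(g1)[cols]),
                      .data$subject, .data$predicate, .data$object)
  b <- dplyr::arrange(dplyr::distinct(tibble::as_tibble(g2)[cols]),
                      .data$subject, .data$predicate, .data$object)
  isTRUE(all.equal(as.data.frame(a), as.data.frame(b), check.attributes = FALSE))
}

# shortest decimal string that parses back to exactly the same double,
# so coordinates survive graph round trips bit-exactly
lexical_number <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) stop("non-finite coordinate value", call. = FALSE)
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    formatC(v, digits = 17, format = "g")
  }, character(1), USE.NAMES = FALSE)
}

#' Map an observation table into the knowledge graph
#'
#' Each record becomes a node `{foo}observation_{obs_id}` typed as a GPS
#' observation and carrying latitude, longitude, local date and local time
#' literals plus links to the sensor node and the feature-of-interest
#' (animal) node: seven observation-scoped triples per record.  A small
#' scaffold types the sensor and animal nodes.  Node IRIs are deterministic
#' functions of `obs_id`, so re-runs reproduce the same graph.
#'
#' @param table observation tibble with at least `obs_id`, `local_date`,
#'   `local_time`, `latitude`, `longitude`.
#' @param vocab a [foo_vocabulary()].
#' @return a triple-graph tibble.
#' @export
map_observations_to_graph <- function(table, vocab = foo_vocabulary()) {
  need <- c("obs_id", "local_date", "local_time", "latitude", "longitude")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    stop("observation table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(table$obs_id)) {
    dup <- unique(table$obs_id[duplicated(table$obs_id)])
    stop("duplicate obs_id: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  scaffold <- tg_rows(
    subject = c(vocab$sensor_node, vocab$foi_node),
    predicate = RDF_TYPE,
    object = c(vocab$class_sensor, vocab$class_animal),
    object_type = "iri"
  )
  if (nrow(table) == 0) return(as_triple_graph(scaffold))
  check_coords(table$latitude, table$longitude)
  obs <- paste0(vocab$foo_ns, "observation_", table$obs_id)
  triples <- dplyr::bind_rows(
    tg_rows(obs, RDF_TYPE, vocab$class_observation, "iri"),
    tg_rows(obs, vocab$p_lat, lexical_number(table$latitude), "literal", vocab$xsd_float),
    tg_rows(obs, vocab$p_lon, lexical_number(table$longitude), "literal", vocab$xsd_float),
    tg_rows(obs, vocab$p_date, as.character(table$local_date), "literal", vocab$xsd_date),
    tg_rows(obs, vocab$p_time, as.character(table$local_time), "literal", vocab$xsd_time),
    tg_rows(obs, vocab$sensor_link, vocab$sensor_node, "iri"),
    tg_rows(obs, vocab$foi_link, vocab$foi_node, "iri"),
    scaffold
  )
  as_triple_graph(triples)
}

#' Add (or replace) the plantation hazard node
#'
#' Adds a node typed as an oil-palm plantation with WGS84 coordinate
#' literals.  If the node already exists, the call errors unless
#' `replace = TRUE`, in which case the coordinates are updated in place.
#'
#' @param graph a triple-graph tibble.
#' @param latitude,longitude plantation site, decimal degrees.
#' @param vocab a [foo_vocabulary()].
#' @param replace replace an existing plantation node instead of erroring.
#' @return the updated triple graph.
#' @export
add_plantation <- function(graph, latitude, longitude,
                           vocab = foo_vocabulary(), replace = FALSE) {
  check_coords(latitude, longitude)
  present <- any(graph$subject == vocab$plantation_node &
                   graph$predicate == RDF_TYPE &
                   graph$object == vocab$class_plantation)
  if (present) {
    if (!replace) {
      stop("plantation node already present; use replace = TRUE to update",
           call. = FALSE)
    }
    graph <- graph[!(graph$subject == vocab$plantation_node &
                       graph$predicate %in% c(RDF_TYPE, vocab$p_lat, vocab$p_lon)), ]
  }
  new <- dplyr::bind_rows(
    tg_rows(vocab$plantation_node, RDF_TYPE, vocab$class_plantation, "iri"),
    tg_rows(vocab$plantation_node, vocab$p_lat, lexical_number(latitude),
            "literal", vocab$xsd_float),
    tg_rows(vocab$plantation_node, vocab$p_lon, lexical_number(longitude),
            "literal", vocab$xsd_float)
  )
  as_triple_graph(dplyr::bind_rows(graph, new))
}

prop_table <- function(graph, predicate, name) {
  out <- graph[graph$predicate == predicate, c("subject", "object")]
  names(out) <- c("subject", name)
  dplyr::distinct(out, .data$subject, .keep_all = TRUE)
}

#' Extract observation rows from the graph
#'
#' SPARQL SELECT semantics over the basic graph pattern `{ ?obs a
#' foo:gPSObservation ; geo:latitude ?lat ; geo:longitude ?long ;
#' foo:localDate ?d ; foo:localTime ?t }`: one row per observation that
#' carries all four properties, ordered by (date, time).  Observations
#' missing any property are skipped and reported in a warning (basic graph
#' patterns only match complete solutions).
#'
#' @param graph a triple-graph tibble.
#' @param vocab a [foo_vocabulary()].
#' @return a tibble with columns `latitude`, `longitude` (numeric),
#'   `local_date`, `local_time` (character), ordered chronologically.
#' @export
select_observations <- function(graph, vocab = foo_vocabulary()) {
  subjects <- unique(graph$subject[graph$predicate == RDF_TYPE &
                                     graph$object == vocab$class_observation])
  empty <- tibble::tibble(latitude = double(), longitude = double(),
                          local_date = character(), local_time = character())
  if (length(subjects) == 0) return(empty)
  tab <- tibble::tibble(subject = subjects) |>
    dplyr::inner_join(prop_table(graph, vocab$p_lat, "lat_lex"), by = "subject") |>
    dplyr::inner_join(prop_table(graph, vocab$p_lon, "lon_lex"), by = "subject") |>
    dplyr::inner_join(prop_table(graph, vocab$p_date, "local_date"), by = "subject") |>
    dplyr::inner_join(prop_table(graph, vocab$p_time, "local_time"), by = "subject")
  skipped <- length(subjects) - nrow(tab)
  if (skipped > 0) {
    warning(skipped, " observation(s) missing a required property were skipped",
            call. = FALSE)
  }
  tab |>
    dplyr::mutate(latitude = as.numeric(.data$lat_lex),
                  longitude = as.numeric(.data$lon_lex)) |>
    dplyr::arrange(.data$local_date, .data$local_time) |>
    dplyr::select("latitude", "longitude", "local_date", "local_time")
}

#' Assert the buffer-zone poaching indicator
#'
#' In-process implementation of the distance-rule semantics: for every GPS
#' observation with coordinates, compute the haversine distance to the
#' plantation node and bind `foo:poaching` to 1 when the distance is within
#' `radius_km` (inclusive `<=`) and 0 otherwise.  Re-application replaces
#' existing flags rather than duplicating them, so the rule is idempotent;
#' no other triple is removed.
#'
#' @param graph a triple-graph tibble containing a plantation node.
#' @param vocab a [foo_vocabulary()].
#' @param radius_km buffer radius, kilometres (default 5).
#' @param radius_earth_km sphere radius for the haversine distance.
#' @return the updated graph, with the number of observations annotated in
#'   attribute `"n_annotated"`.
#' @export
apply_poaching_rule <- function(graph, vocab = foo_vocabulary(),
                                radius_km = 5,
                                radius_earth_km = EARTH_RADIUS_KM) {
  plat <- graph$object[graph$subject == vocab$plantation_node &
                         graph$predicate == vocab$p_lat]
  plon <- graph$object[graph$subject == vocab$plantation_node &
                         graph$predicate == vocab$p_lon]
  if (length(plat) == 0 || length(plon) == 0) {
    stop("poaching rule error: no plantation node with coordinates in the graph",
         call. = FALSE)
  }
  subjects <- unique(graph$subject[graph$predicate == RDF_TYPE &
                                     graph$object == vocab$class_observation])
  coords <- tibble::tibble(subject = subjects) |>
    dplyr::inner_join(prop_table(graph, vocab$p_lat, "lat_lex"), by = "subject") |>
    dplyr::inner_join(prop_table(graph, vocab$p_lon, "lon_lex"), by = "subject")
  if (nrow(coords) == 0) {
    out <- as_triple_graph(graph)
    attr(out, "n_annotated") <- 0L
    return(out)
  }
  flag <- within_buffer(as.numeric(coords$lat_lex), as.numeric(coords$lon_lex),
                        as.numeric(plat[1]), as.numeric(plon[1]),
                        radius_km = radius_km,
                        radius_earth_km = radius_earth_km)
  graph <- graph[!(graph$predicate == vocab$p_poaching &
                     graph$subject %in% coords$subject), ]
  new <- tg_rows(coords$subject, vocab$p_poaching, as.character(flag),
                 "literal", vocab$xsd_integer)
  out <- as_triple_graph(dplyr::bind_rows(graph, new))
  attr(out, "n_annotated") <- nrow(coords)
  out
}

#' Insert model predictions as observation nodes
#'
#' Each predicted fix becomes a GPS-observation node (so the poaching rule
#' covers it on the next application) carrying the four standard literals,
#' plus one provenance triple in the extension namespace marking it as
#' model-generated.
#'
#' @param graph a triple-graph tibble.
#' @param predictions tibble with `latitude`, `longitude`, `local_date`,
#'   `local_time`; all values must be finite/complete.
#' @param vocab a [foo_vocabulary()].
#' @return the updated graph.
#' @export
insert_predictions <- function(graph, predictions, vocab = foo_vocabulary()) {
  if (nrow(predictions) == 0) return(as_triple_graph(graph))
  if (anyNA(predictions) || any(!is.finite(predictions$latitude)) ||
      any(!is.finite(predictions$longitude))) {
    stop("predictions must be complete and finite", call. = FALSE)
  }
  check_coords(predictions$latitude, predictions$longitude)
  prefix <- paste0(vocab$foo_ns, "observation_pred_")
  offset <- sum(startsWith(unique(graph$subject), prefix))
  obs <- paste0(prefix, offset + seq_len(nrow(predictions)))
  new <- dplyr::bind_rows(
    tg_rows(obs, RDF_TYPE, vocab$class_observation, "iri"),
    tg_rows(obs, vocab$p_lat, lexical_number(predictions$latitude),
            "literal", vocab$xsd_float),
    tg_rows(obs, vocab$p_lon, lexical_number(predictions$longitude),
            "literal", vocab$xsd_float),
    tg_rows(obs, vocab$p_date, as.character(predictions$local_date),
            "literal", vocab$xsd_date),
    tg_rows(obs, vocab$p_time, as.character(predictions$local_time),
            "literal", vocab$xsd_time),
    tg_rows(obs, vocab$p_predicted_by, vocab$model_node, "iri")
  )
  as_triple_graph(dplyr::bind_rows(graph, new))
}

#' Construct the poaching-status report subgraph
#'
#' CONSTRUCT-style subgraph: for every observation that already carries a
#' poaching flag, keep exactly its type, local date, latitude, longitude
#' and poaching triples (five per observation).  Before the rule has been
#' applied the pattern matches nothing and the result is empty.
#'
#' @param graph a triple-graph tibble.
#' @param vocab a [foo_vocabulary()].
#' @return a triple-graph tibble (the report subgraph).
#' @export
construct_poaching_report <- function(graph, vocab = foo_vocabulary()) {
  flagged <- unique(graph$subject[graph$predicate == vocab$p_poaching])
  typed <- unique(graph$subject[graph$predicate == RDF_TYPE &
                                  graph$object == vocab$class_observation])
  keep_subj <- intersect(flagged, typed)
  keep <- graph$subject %in% keep_subj &
    ((graph$predicate == RDF_TYPE & graph$object == vocab$class_observation) |
       graph$predicate %in% c(vocab$p_date, vocab$p_lat, vocab$p_lon,
                              vocab$p_poaching))
  as_triple_graph(graph[keep, ])
}

#' Count triples whose subject is an observation node
#'
#' Convenience used in manifests: number of distinct GPS-observation nodes
#' in the graph.
#'
#' @param graph a triple-graph tibble.
#' @param vocab a [foo_vocabulary()].
#' @return integer count.
#' @export
count_observation_nodes <- function(graph, vocab = foo_vocabulary()) {
  length(unique(graph$subject[graph$predicate == RDF_TYPE &
                                graph$object == vocab$class_observation]))
}
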