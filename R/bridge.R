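#' JSON message bridge between agents and environments
#'
#' Observations, rewards and actions cross process boundaries as small JSON
#' messages with a fixed, versioned schema:
#' \code{\{kind, dim, payload, timestamp\}} where \code{kind} is one of
#' \code{"observation"}, \code{"reward"}, \code{"action"}, \code{dim} the
#' declared payload length and \code{payload} a numeric vector (length 1
#' for discrete indices and scalar rewards).  Messages round-trip through
#' serialization exactly (full double precision).
#'
#' Two transports are provided:
#' \itemize{
#'   \item a \emph{loopback} transport (\code{\link{bridge_env}}) that
#'     passes every observation, reward and action of an in-process
#'     environment through encode/decode, giving a lockstep bridge whose
#'     runs are bit-identical to direct in-process runs;
#'   \item a \emph{TCP} transport (\code{\link{serve_env}} /
#'     \code{\link{remote_env}}) exposing an environment on a socket with a
#'     synchronous request-reply handshake, for running the environment in
#'     a separate process.
#' }
#' The wrapper this mirrors runs four concurrent workers (environment
#' stepper, action subscriber, observation publisher, reward publisher)
#' over publish-subscribe sockets with latest-value buffers; a
#' single-threaded R process multiplexes those four roles in one event
#' loop, and the lockstep handshake replaces free-running asynchrony so
#' that runs are exactly reproducible.  If no action has been received yet
#' the stepper uses a configured default action.
#'
#' @name bridge
NULL

#' Encode an environment message as JSON
#'
#' @param kind \code{"observation"}, \code{"reward"} or \code{"action"}.
#' @param payload numeric vector (or single integer for discrete values).
#' @param timestamp numeric time stamp in ms.
#' @return A single-line JSON string.
#' @export
encode_message <- function(kind = c("observation", "reward", "action"),
                           payload, timestamp = 0) {
  kind <- match.arg(kind)
  payload <- as.numeric(payload)
  if (length(payload) == 0) stop("empty payload")
  assert_finite(payload, "payload")
  jsonlite::toJSON(list(kind = kind, dim = length(payload),
                        payload = payload, timestamp = timestamp),
                   auto_unbox = TRUE, digits = I(17))
}

#' Decode an environment message from JSON
#'
#' Schema violations raise an error naming the offending field; malformed
#' JSON raises a parse error rather than crashing the caller.
#'
#' @param bytes a JSON string produced by \code{\link{encode_message}}.
#' @return List with fields \code{kind}, \code{dim}, \code{payload},
#'   \code{timestamp}.
#' @export
decode_message <- function(bytes) {
  msg <- tryCatch(jsonlite::fromJSON(bytes),
                  error = function(e) stop("malformed message: ",
                                           conditionMessage(e), call. = FALSE))
  for (f in c("kind", "dim", "payload", "timestamp")) {
    if (is.null(msg[[f]])) stop("message missing field '", f, "'",
                                call. = FALSE)
  }
  if (!msg$kind %in% c("observation", "reward", "action"))
    stop("invalid value in field 'kind'", call. = FALSE)
  msg$payload <- as.numeric(msg$payload)
  if (length(msg$payload) != msg$dim)
    stop("field 'payload' length does not match field 'dim'", call. = FALSE)
  msg
}

#' Loopback bridge around an in-process environment
#'
#' Wraps an environment so that every action sent to it and every
#' observation/reward returned from it passes through
#' \code{\link{encode_message}} / \code{\link{decode_message}}.  Because the
#' handshake is lockstep and serialization is exact, training through this
#' bridge is bit-identical to training on the bare environment.
#'
#' @param env an environment with \code{env_reset}/\code{env_step}.
#' @return An environment object of class \code{c("bridge_env", "rl_env")}.
#' @export
bridge_env <- function(env) {
  e <- new.env(parent = emptyenv())
  e$inner <- env
  e$n_actions <- env$n_actions
  e$obs_bounds <- env$obs_bounds
  class(e) <- c("bridge_env", "rl_env")
  e
}

#' @export
env_reset.bridge_env <- function(env) {
  obs <- env_reset(env$inner)
  decode_message(encode_message("observation", obs))$payload
}

#' @export
env_step.bridge_env <- function(env, action) {
  a <- decode_message(encode_message("action", action))$payload
  res <- env_step(env$inner, a)
  obs <- decode_message(encode_message("observation", res$observation,
                                       timestamp = env$inner$cum_reward))
  rew <- decode_message(encode_message("reward", res$reward))
  list(observation = obs$payload, reward = rew$payload, done = res$done)
}

# cum_reward of the wrapped environment, used by reward bookkeeping checks
#' @export
`$.bridge_env` <- function(x, name) {
  if (exists(name, envir = x, inherits = FALSE)) get(name, envir = x)
  else get(name, envir = get("inner", envir = x))
}

#' Serve an environment over a TCP socket (lockstep handshake)
#'
#' Blocking server: binds a localhost port and answers newline-delimited
#' JSON requests.  An \code{action} message steps the environment and the
#' reply carries the observation (with the reward and done flag attached);
#' the control requests \code{\{"kind": "reset"\}} and
#' \code{\{"kind": "stop"\}} reset the environment / shut the server down.
#' Requests that fail to decode are logged and skipped, not fatal.  A
#' stepper invoked before any action message uses \code{default_action}.
#' Intended to be run in a separate R process (see
#' \code{\link{remote_env}} for the client side).
#'
#' @param env the environment to expose.
#' @param port TCP port to listen on.
#' @param default_action action used if a step is requested before any
#'   action message has arrived.
#' @param max_requests stop after this many requests (default infinite).
#' @return Invisibly, the number of requests served.
#' @export
serve_env <- function(env, port = 6789, default_action = 0L,
                      max_requests = Inf) {
  con <- socketConnection(host = "127.0.0.1", port = port, server = TRUE,
                          blocking = TRUE, open = "r+", timeout = 60)
  on.exit(close(con))
  last_action <- default_action
  served <- 0
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) break
    served <- served + 1
    reply <- tryCatch({
      req <- jsonlite::fromJSON(line)
      if (identical(req$kind, "stop")) {
        writeLines('{"kind":"stopped"}', con)
        break
      } else if (identical(req$kind, "reset")) {
        obs <- env_reset(env)
        jsonlite::toJSON(list(kind = "observation", dim = length(obs),
                              payload = as.numeric(obs), timestamp = 0,
                              reward = 0, done = FALSE),
                         auto_unbox = TRUE, digits = I(17))
      } else {
        if (identical(req$kind, "action"))
          last_action <- decode_message(line)$payload
        res <- env_step(env, last_action)
        obs <- as.numeric(res$observation)
        jsonlite::toJSON(list(kind = "observation", dim = length(obs),
                              payload = obs, timestamp = 0,
                              reward = res$reward, done = res$done),
                         auto_unbox = TRUE, digits = I(17))
      }
    }, error = function(e) {
      jsonlite::toJSON(list(kind = "error",
                            message = conditionMessage(e)),
                       auto_unbox = TRUE)
    })
    writeLines(as.character(reply), con)
    if (served >= max_requests) break
  }
  invisible(served)
}

#' Client for an environment served over TCP
#'
#' Connects to a \code{\link{serve_env}} server and exposes the remote
#' environment behind the usual \code{env_reset}/\code{env_step} protocol.
#'
#' @param port TCP port of the server.
#' @param host server host (default localhost).
#' @param n_actions number of actions of the remote environment (the
#'   protocol does not carry it).
#' @param timeout socket timeout in seconds.
#' @return An environment object of class \code{c("remote_env", "rl_env")}.
#' @export
remote_env <- function(port = 6789, host = "127.0.0.1", n_actions = 4L,
                       timeout = 60) {
  con <- socketConnection(host = host, port = port, server = FALSE,
                          blocking = TRUE, open = "r+", timeout = timeout)
  e <- new.env(parent = emptyenv())
  e$con <- con
  e$n_actions <- as.integer(n_actions)
  e$cum_reward <- 0
  class(e) <- c("remote_env", "rl_env")
  e
}

#' @noRd
remote_request <- function(env, line) {
  writeLines(line, env$con)
  reply <- readLines(env$con, n = 1)
  if (length(reply) == 0) stop("server closed the connection")
  jsonlite::fromJSON(reply)
}

#' @export
env_reset.remote_env <- function(env) {
  rep <- remote_request(env, '{"kind":"reset"}')
  as.numeric(rep$payload)
}

#' @export
env_step.remote_env <- function(env, action) {
  rep <- remote_request(env, as.character(encode_message("action", action)))
  if (identical(rep$kind, "error")) stop("server error: ", rep$message)
  env$cum_reward <- env$cum_reward + rep$reward
  list(observation = as.numeric(rep$payload), reward = rep$reward,
       done = isTRUE(rep$done))
}

#' Stop a served environment
#'
#' @param env a \code{remote_env}.
#' @return Invisibly \code{TRUE}.
#' @export
remote_stop <- function(env) {
  try(writeLines('{"kind":"stop"}', env$con), silent = TRUE)
  try(close(env$con), silent = TRUE)
  invisible(TRUE)
}
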