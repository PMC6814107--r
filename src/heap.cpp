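// Indexed binary min-heap for the event calendar.
// Events are ordered by (time, priority, insertion sequence); the insertion
// sequence doubles as the event id/handle. Cancellation marks the event dead
// in O(1); dead events are discarded lazily at pop time. The heap also
// stores, per event, an integer kind code and a scalar numeric payload so
// the R side does not have to maintain growing per-event vectors (non-scalar
// payloads are kept in an R-side hash keyed by event id).

#include <Rcpp.h>
#include <vector>

struct EventHeap {
  std::vector<double> time;   // indexed by id-1
  std::vector<int>    prio;
  std::vector<int>    kind;
  std::vector<double> pay;
  std::vector<char>   alive;
  std::vector<int>    heap;   // ids, heap-ordered
  int n_alive = 0;

  bool lt(int a, int b) const {
    if (time[a - 1] != time[b - 1]) return time[a - 1] < time[b - 1];
    if (prio[a - 1] != prio[b - 1]) return prio[a - 1] < prio[b - 1];
    return a < b;
  }
  void sift_up(size_t i) {
    while (i > 0) {
      size_t p = (i - 1) / 2;
      if (lt(heap[i], heap[p])) { std::swap(heap[i], heap[p]); i = p; }
      else break;
    }
  }
  void sift_down(size_t i) {
    size_t n = heap.size();
    for (;;) {
      size_t l = 2 * i + 1, r = l + 1, m = i;
      if (l < n && lt(heap[l], heap[m])) m = l;
      if (r < n && lt(heap[r], heap[m])) m = r;
      if (m == i) break;
      std::swap(heap[i], heap[m]);
      i = m;
    }
  }
  int push(double t, int p, int k, double pl) {
    time.push_back(t);
    prio.push_back(p);
    kind.push_back(k);
    pay.push_back(pl);
    alive.push_back(1);
    int id = (int)time.size();
    heap.push_back(id);
    sift_up(heap.size() - 1);
    n_alive++;
    return id;
  }
  bool cancel(int id) {
    if (id < 1 || id > (int)alive.size() || !alive[id - 1]) return false;
    alive[id - 1] = 0;
    n_alive--;
    return true;
  }
  void drop_root() {
    heap[0] = heap.back();
    heap.pop_back();
    if (!heap.empty()) sift_down(0);
  }
  void settle() {
    while (!heap.empty() && !alive[heap[0] - 1]) drop_root();
  }
  int peek() {
    settle();
    return heap.empty() ? NA_INTEGER : heap[0];
  }
};

// [[Rcpp::export]]
SEXP heap_new() {
  Rcpp::XPtr<EventHeap> p(new EventHeap(), true);
  return p;
}

// [[Rcpp::export]]
int heap_push(SEXP h, double time, int priority, int kind, double payload) {
  return Rcpp::XPtr<EventHeap>(h)->push(time, priority, kind, payload);
}

// [[Rcpp::export]]
bool heap_cancel(SEXP h, int id) {
  return Rcpp::XPtr<EventHeap>(h)->cancel(id);
}

// Pop the next event if its time is <= horizon.
// Returns numeric(4): id, time, kind, payload; numeric(0) when none.
// [[Rcpp::export]]
Rcpp::NumericVector heap_pop_le(SEXP h, double horizon) {
  EventHeap *e = Rcpp::XPtr<EventHeap>(h).get();
  int id = e->peek();
  if (id == NA_INTEGER || e->time[id - 1] > horizon) {
    return Rcpp::NumericVector(0);
  }
  e->alive[id - 1] = 0;
  e->n_alive--;
  e->drop_root();
  return Rcpp::NumericVector::create(
    (double)id, e->time[id - 1], (double)e->kind[id - 1], e->pay[id - 1]);
}

// [[Rcpp::export]]
int heap_peek(SEXP h) {
  return Rcpp::XPtr<EventHeap>(h)->peek();
}

// [[Rcpp::export]]
double heap_time(SEXP h, int id) {
  return Rcpp::XPtr<EventHeap>(h)->time[id - 1];
}

// [[Rcpp::export]]
int heap_size(SEXP h) {
  return Rcpp::XPtr<EventHeap>(h)->n_alive;
}

// [[Rcpp::export]]
bool heap_is_alive(SEXP h, int id) {
  EventHeap *e = Rcpp::XPtr<EventHeap>(h).get();
  if (id < 1 || id > (int)e->alive.size()) return false;
  return e->alive[id - 1] != 0;
}
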