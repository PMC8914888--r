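# Build with the system toolchain so the shared object links against the
# host C library that the dynamic loader actually resolves at run time.
RCPP_INC = $(shell "$(R_HOME)/bin/Rscript" -e 'cat(system.file("include", package="Rcpp"))')
CXX = g++
CXXFLAGS = -O2 -fPIC -std=gnu++17
CPPFLAGS = -I"$(R_HOME)/include" -I"$(RCPP_INC)" -DNDEBUG
OBJECTS = RcppExports.o unwrap.o tfce.o hull.o medfilt.o

all: dentateqsm.so

dentateqsm.so: $(OBJECTS)
	$(CXX) -shared -o $@ $(OBJECTS) -L"$(R_HOME)/lib" -lR

%.o: %.cpp
	$(CXX) $(CXXFLAGS) $(CPPFLAGS) -c $< -o $@

clean:
	rm -f $(OBJECTS) dentateqsm.so
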