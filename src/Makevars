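# HDF5 lives in the same prefix as R itself (R_HOME = <prefix>/lib/R).
PKG_CPPFLAGS = -I$(R_HOME)/../../include
PKG_LIBS = -L$(R_HOME)/../../lib -lhdf5 -Wl,-rpath,$(R_HOME)/../../lib
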