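# FFTW3 lives in the same prefix as R itself (conda-style layout); fall back
# to the default search path when that guess is wrong.
PKG_CPPFLAGS = -I$(R_HOME)/../../include
PKG_LIBS = -L$(R_HOME)/../../lib -lfftw3
PKG_CXXFLAGS = -O3
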